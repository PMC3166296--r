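test_that("hypergeometric tail handles the closed-form cases and rejects bad parameters", {
  expect_identical(hypergeometric_tail_p(10, 5, 5, 0), 1)
  expect_equal(hypergeometric_tail_p(10, 5, 5, 5), 1 / choose(10, 5),
               tolerance = 1e-14)
  expect_equal(hypergeometric_tail_p(20, 6, 7, 4),
               enumeration_tail_p(20, 6, 7, 4), tolerance = 1e-14)
  expect_error(hypergeometric_tail_p(10, 5, 5, 6), "exceeds min")
  expect_error(hypergeometric_tail_p(10, 11, 5, 2), "exceed the universe")
  expect_error(hypergeometric_tail_p(10, -1, 5, 0), "non-negative")
})

test_that("log-space tail equals direct enumeration over a small-universe grid", {
  worst <- 0
  for (N in 1:12) {
    for (M in 0:N) {
      for (K in 0:N) {
        for (x in 0:min(M, K)) {
          worst <- max(worst, abs(hypergeometric_tail_p(N, M, K, x) -
                                    enumeration_tail_p(N, M, K, x)))
        }
      }
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("tail probability agrees with the survival-function route for large universes", {
  set.seed(101)
  for (i in 1:200) {
    N <- sample(50:100000, 1)
    M <- sample.int(min(N, 2000), 1)
    K <- sample.int(min(N, 2000), 1)
    cap <- min(M, K, ceiling(M * K / N + 10 * sqrt(M * K / N + 1)))
    x <- sample.int(cap + 1, 1) - 1
    mine <- hypergeometric_tail_p(N, M, K, x)
    ref <- stats::phyper(x - 1, M, N - M, K, lower.tail = FALSE)
    expect_equal(mine, ref, tolerance = 1e-9)
  }
})

test_that("tail probability is symmetric in (M, K) and non-increasing in x", {
  set.seed(202)
  for (i in 1:1000) {
    N <- sample(2:500, 1)
    M <- sample.int(N, 1)
    K <- sample.int(N, 1)
    x <- sample.int(min(M, K) + 1, 1) - 1
    expect_equal(hypergeometric_tail_p(N, M, K, x),
                 hypergeometric_tail_p(N, K, M, x), tolerance = 1e-12)
    if (x >= 1)
      expect_lte(hypergeometric_tail_p(N, M, K, x),
                 hypergeometric_tail_p(N, M, K, x - 1) + 1e-15)
  }
})

test_that("test_pair counts overlap and hits the monotone endpoints", {
  universe <- sprintf("g%04d", 1:1000)
  a <- pcs("A", 4, 10, "up", universe[1:50])
  b <- pcs("B", 4, 10, "up", universe[101:150])
  disjoint <- test_pair(a, b, 1000)
  expect_identical(disjoint$x, 0L)
  expect_identical(disjoint$p, 1)
  expect_identical(disjoint$relation, "synchronous")

  inside <- pcs("B", 4, 10, "down", universe[1:80])  # a is a subset
  t_in <- test_pair(a, inside, 1000)
  expect_identical(t_in$x, 50L)
  expect_identical(t_in$relation, "asynchronous")
  # full containment is the minimal-p endpoint for fixed (N, M, K)
  for (x in 0:49)
    expect_gte(hypergeometric_tail_p(1000, 50, 80, x), t_in$p)

  expect_error(test_pair(a, a, 1000), "never tested against itself")
})

test_that("tail probability matches a permutation oracle within Monte-Carlo error", {
  set.seed(303)
  universe <- sprintf("g%04d", 1:1000)
  a_genes <- sample(universe, 40)
  b_genes <- c(sample(a_genes, 3), sample(setdiff(universe, a_genes), 37))
  tst <- test_pair(pcs("A", 4, 10, "up", a_genes),
                   pcs("B", 4, 10, "up", b_genes), 1000)
  expect_identical(tst$x, 3L)

  n_perm <- 20000
  hits <- sum(vapply(seq_len(n_perm), function(i)
    length(intersect(a_genes, sample(universe, 40))) >= tst$x, 0L))
  p_hat <- hits / n_perm
  expect_lt(abs(tst$p - p_hat),
            4 * sqrt(p_hat * (1 - p_hat) / n_perm) + 1e-6)
})

test_that("phase network connects identical sets, skips empty ones, and types relations", {
  universe <- sprintf("g%05d", 1:10000)
  shared <- universe[1:100]
  sets <- list(pcs("A", 4, 10, "up", shared),
               pcs("A", 4, 10, "down", universe[201:250]),
               pcs("B", 4, 10, "up", shared),
               pcs("B", 4, 10, "down", character()))
  net <- build_phase_network(sets, N = 10000, threshold = 0.005)
  expect_s3_class(net, "AssociationNetwork")
  # B_down empty: only A_up~B_up and A_down~B_up are tested
  expect_identical(net$n_tests, 2L)
  expect_identical(nrow(net$edges), 1L)
  expect_identical(net$edges$relation, "synchronous")
  expect_identical(sort(c(net$edges$node_a, net$edges$node_b)),
                   c("A_10Mv4M_up", "B_10Mv4M_up"))

  s <- summarize_network(net)
  expect_identical(s$sync_edges + s$async_edges, nrow(net$edges))
  expect_identical(s$connected_nodes + s$stochastic_nodes, nrow(net$nodes))
  expect_identical(s$connected_nodes, 2L)
  expect_true(all(!net$nodes$connected[net$nodes$node_name %in%
                                         c("A_10Mv4M_down", "B_10Mv4M_down")]))

  # an up-down overlap is an asynchronous edge
  sets2 <- list(pcs("A", 4, 10, "up", shared),
                pcs("B", 4, 10, "down", shared))
  net2 <- build_phase_network(sets2, N = 10000, threshold = 0.005)
  expect_identical(net2$edges$relation, "asynchronous")

  expect_error(build_phase_network(
    list(pcs("A", 4, 10, "up", shared), pcs("B", 10, 18, "up", shared)),
    N = 10000), "single phase")
})

test_that("independent random sets produce edges at about the nominal rate", {
  set.seed(404)
  universe <- sprintf("g%04d", 1:2000)
  threshold <- 0.05
  n_rep <- 150L
  sig <- 0L
  total <- 0L
  for (r in seq_len(n_rep)) {
    sets <- list(pcs("A", 4, 10, "up", sample(universe, 200)),
                 pcs("A", 4, 10, "down", sample(universe, 200)),
                 pcs("B", 4, 10, "up", sample(universe, 200)),
                 pcs("B", 4, 10, "down", sample(universe, 200)))
    net <- build_phase_network(sets, N = 2000, threshold = threshold,
                               keep_tests = TRUE)
    total <- total + net$n_tests
    sig <- sig + sum(net$tests$p < threshold)
  }
  expect_identical(total, 4L * n_rep)  # 4 directional combos per tissue pair
  rate <- sig / total
  # discrete test: at or conservatively below the nominal level
  expect_lt(rate, threshold + 3 * sqrt(threshold * (1 - threshold) / total))
  expect_gt(rate, 0.015)
})

test_that("edge lists and GraphML exports are written with their settings", {
  universe <- sprintf("g%05d", 1:10000)
  sets <- list(pcs("A", 4, 10, "up", universe[1:100]),
               pcs("B", 4, 10, "up", universe[1:100]),
               pcs("C", 4, 10, "down", universe[200:220]))
  net <- build_phase_network(sets, N = 10000, threshold = 0.005)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_edge_list(net, tsv)
  edges <- utils::read.delim(tsv)
  expect_identical(nrow(edges), 1L)
  expect_identical(edges$threshold, 0.005)
  expect_identical(edges$N, 10000L)

  write_graphml(net, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 1)
  expect_setequal(igraph::vertex_attr(g, "tissue"), c("A", "B", "C"))
})
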