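test_that("the two-tissue worked example is called up in different phases, and jointly at the endpoints", {
  ds <- slc24a2_fixture()
  sets <- build_change_sets(ds, change_criterion("fold_change"))
  expect_length(sets, 12L)  # 2 tissues x 3 phases x 2 directions
  nonempty <- names(Filter(function(s) length(s$genes) > 0, sets))
  expect_setequal(nonempty, c("A_10Mv4M_up", "H_18Mv10M_up"))

  # the endpoint contrast hides the asynchrony: both tissues rise 4M -> 24M
  for (tissue in c("A", "H")) {
    ends <- detect_fold_change(ds, age_phase(tissue, 4, 24))
    expect_identical(ends$up$genes, "Slc24a2")
    expect_length(ends$down$genes, 0L)
  }
})

test_that("fold-change boundary is inclusive and constant series are never called", {
  vals <- rbind(exact = c(8, 9), below = c(8, 8.999), flat = c(5, 5),
                down = c(9, 7.5))
  colnames(vals) <- c("X_4M", "X_10M")
  ds <- expression_dataset(
    vals, data.frame(sample_id = colnames(vals), tissue = "X",
                     age = c(4, 10)), scale = "log2")
  res <- detect_fold_change(ds, age_phase("X", 4, 10))
  expect_identical(res$up$genes, "exact")   # log2 delta exactly 1: "at least"
  expect_identical(res$down$genes, "down")
  expect_identical(res$up$node_name, "X_10Mv4M_up")

  # linear-scale equivalent of the same rule
  lin <- expression_dataset(
    2^vals, data.frame(sample_id = colnames(vals), tissue = "X",
                       age = c(4, 10)), scale = "linear")
  res_lin <- detect_fold_change(lin, age_phase("X", 4, 10))
  expect_identical(res_lin$up$genes, res$up$genes)
  expect_identical(res_lin$down$genes, res$down$genes)

  expect_error(detect_fold_change(ds, age_phase("Y", 4, 10)), "tissue absent")
  expect_error(detect_fold_change(ds, age_phase("X", 4, 18)), "age absent")
})

test_that("swapping the two ages of a phase swaps up and down sets exactly", {
  sim <- simulate_dataset(simulation_config(
    n_genes = 400, tissues = "T", ages = c(4, 10), replicates = 3,
    noise_sd = 0.8, seed = 11))
  ds <- sim$dataset
  swapped <- ds
  swapped$samples$age <- ifelse(swapped$samples$age == 4, 10, 4)

  phase <- age_phase("T", 4, 10)
  for (detect in list(detect_fold_change,
                      function(d, p) suppressMessages(detect_z_test(d, p)))) {
    fwd <- detect(ds, phase)
    rev <- detect(swapped, phase)
    expect_setequal(fwd$up$genes, rev$down$genes)
    expect_setequal(fwd$down$genes, rev$up$genes)
  }
})

test_that("z test matches an independently computed normal tail probability", {
  vals <- rbind(shift = c(0, 0.1, -0.1, 0.2, 0.3, 0.1),
                big = c(0, 0.1, -0.1, 1.0, 1.1, 0.9),
                null = c(1, 2, 3, 1, 2, 3))
  samples <- data.frame(sample_id = paste0("s", 1:6), tissue = "X",
                        age = rep(c(4, 10), each = 3),
                        replicate = rep(1:3, 2))
  colnames(vals) <- samples$sample_id
  ds <- expression_dataset(vals, samples, scale = "log2")
  phase <- age_phase("X", 4, 10)

  # oracle: per-gene Welch z and its standard-normal upper tail, computed
  # with stats::var/pnorm directly on the raw numbers
  oracle_p <- function(from, to) {
    z <- (mean(to) - mean(from)) /
      sqrt(stats::var(to) / length(to) + stats::var(from) / length(from))
    stats::pnorm(z, lower.tail = FALSE)
  }
  p_shift <- oracle_p(vals["shift", 1:3], vals["shift", 4:6])
  expect_equal(p_shift, 0.0071527, tolerance = 1e-4)  # frozen from oracle

  # bracket the implementation's p with the calling threshold
  called_at <- function(alpha)
    "shift" %in% detect_z_test(ds, phase, change_criterion(
      "z_test", z_alpha = alpha))$up$genes
  expect_false(called_at(p_shift * 0.99))
  expect_true(called_at(p_shift * 1.01))

  res <- detect_z_test(ds, phase, change_criterion("z_test", z_alpha = 0.01))
  # both shifted genes clear alpha = 0.01 (p_shift ~ 0.0072, p_big ~ 0)
  expect_setequal(res$up$genes, c("shift", "big"))
  expect_false("null" %in% res$up$genes)    # identical groups: z = 0, p = 0.5
  expect_false("null" %in% res$down$genes)
})

test_that("z test skips genes with too few replicates or zero variance, and counts them", {
  vals <- rbind(ok = c(0, 0.2, 5, 5.2),
                oneRep = c(0, NA, 5, 5.2),
                constEq = c(3, 3, 3, 3))
  samples <- data.frame(sample_id = paste0("s", 1:4), tissue = "X",
                        age = rep(c(4, 10), each = 2))
  colnames(vals) <- samples$sample_id
  ds <- expression_dataset(vals, samples, scale = "log2")
  expect_message(
    res <- detect_z_test(ds, age_phase("X", 4, 10)),
    "skipped 1 gene\\(s\\) with <2 replicates, 1 with zero variance")
  skipped <- attr(res, "skipped")
  expect_equal(skipped[["too_few_replicates"]], 1L)
  expect_equal(skipped[["zero_variance"]], 1L)
  expect_false(any(c("oneRep", "constEq") %in%
                     c(res$up$genes, res$down$genes)))
})

test_that("MAS5 composite criterion needs all three filters to agree", {
  vals <- rbind(gUp = c(7, 8.5), gAbsent = c(7, 8.5), gDown = c(8.5, 7),
                gSmall = c(7, 7.4))
  det <- rbind(gUp = c("P", "P"), gAbsent = c("P", "A"),
               gDown = c("P", "P"), gSmall = c("P", "P"))
  ds <- pooled_dataset(vals, "X", c(4, 10), detection = det)
  phase <- age_phase("X", 4, 10)
  crit <- change_criterion("mas5_composite")

  change_p <- c(gUp = 0.001, gAbsent = 0.001, gDown = 0.9990, gSmall = 0.001)
  res <- detect_mas5_composite(ds, phase, crit, change_p)
  expect_identical(res$up$genes, "gUp")       # p, fold-change and P/P all pass
  expect_identical(res$down$genes, "gDown")   # 1 - 0.9990 = 0.001 < 0.0025
  expect_false("gAbsent" %in% res$up$genes)   # presence filter: P/A fails
  expect_false("gSmall" %in% res$up$genes)    # fold-change below 2

  # change p-value alone is not enough in the other direction either
  res2 <- detect_mas5_composite(
    ds, phase, crit, c(gUp = 0.5, gAbsent = 0.5, gDown = 0.5, gSmall = 0.5))
  expect_length(res2$up$genes, 0L)
  expect_length(res2$down$genes, 0L)

  # without detection calls the presence filter is skipped with a warning
  ds_nodet <- pooled_dataset(vals, "X", c(4, 10))
  expect_warning(
    res3 <- detect_mas5_composite(ds_nodet, phase, crit, change_p),
    "presence filter skipped")
  expect_setequal(res3$up$genes, c("gUp", "gAbsent"))

  expect_error(detect_mas5_composite(ds, phase, crit, NULL), "change_p")
})

test_that("consensus calls require the same direction in both datasets", {
  vals_a <- rbind(g1 = c(7, 8.2), g2 = c(7, 8.2), g3 = c(7, 8.2))
  vals_b <- rbind(g1 = c(7, 8.1), g2 = c(7, 7.2), g3 = c(8.2, 7))
  ds_a <- pooled_dataset(vals_a, "X", c(4, 10))
  ds_b <- pooled_dataset(vals_b, "X", c(4, 10))
  res <- detect_consensus(ds_a, ds_b, age_phase("X", 4, 10))
  expect_identical(res$up$genes, "g1")  # up in both
  expect_length(res$down$genes, 0L)     # g2 unchanged in B, g3 conflicting

  # against itself, consensus reduces to plain fold-change detection
  sim <- simulate_dataset(simulation_config(
    n_genes = 300, tissues = "X", ages = c(4, 10), noise_sd = 0.8, seed = 3))
  phase <- age_phase("X", 4, 10)
  cons <- detect_consensus(sim$dataset, sim$dataset, phase)
  fc <- detect_fold_change(sim$dataset, phase)
  expect_setequal(cons$up$genes, fc$up$genes)
  expect_setequal(cons$down$genes, fc$down$genes)

  # mismatched universes are intersected with a message
  ds_b2 <- ds_b
  rownames(ds_b2$values) <- c("g1", "g2", "gX")
  expect_message(detect_consensus(ds_a, ds_b2, age_phase("X", 4, 10)),
                 "restricting to 2 shared genes")
})

test_that("build_change_sets enumerates 2 x tissues x consecutive phases named sets", {
  sim7 <- simulate_dataset(simulation_config(
    n_genes = 50, tissues = c("H", "P", "A", "C", "K", "L", "B"),
    ages = c(4, 10, 18, 24), seed = 5))
  sets7 <- build_change_sets(sim7$dataset)
  expect_length(sets7, 42L)
  expect_true(all(grepl("^[A-Za-z]+_\\d+Mv\\d+M_(up|down)$", names(sets7))))

  sim16 <- simulate_dataset(simulation_config(
    n_genes = 20, tissues = sprintf("T%02d", 1:16),
    ages = c(1, 6, 16, 24), seed = 6))
  expect_length(build_change_sets(sim16$dataset), 96L)

  # endpoint contrast adds one extra phase per tissue when requested
  expect_length(build_change_sets(sim7$dataset, include_endpoint = TRUE), 56L)

  # a single-age dataset has no phases
  one_age <- pooled_dataset(matrix(8, 1, 1, dimnames = list("g1", NULL)),
                            "X", 4)
  expect_identical(build_change_sets(one_age), list())
})

test_that("z-test call rate converges to the nominal per-tail level as replicates grow", {
  rate_at <- function(n_rep, seed) {
    sim <- simulate_dataset(simulation_config(
      n_genes = 20000, tissues = "T", ages = c(1, 2), replicates = n_rep,
      noise_sd = 1, seed = seed))
    res <- detect_z_test(sim$dataset, age_phase("T", 1, 2),
                         change_criterion("z_test", z_alpha = 0.01))
    (length(res$up$genes) + length(res$down$genes)) / (2 * 20000)
  }
  r5 <- rate_at(5, 21)
  r200 <- rate_at(200, 22)
  # few replicates are anticonservative (the estimated-variance statistic is
  # closer to a t than a normal); the discrepancy shrinks with replicates
  expect_gt(r5, 0.015)
  expect_lt(abs(r200 - 0.01), abs(r5 - 0.01))
  expect_lt(abs(r200 - 0.01), 3 * sqrt(0.01 * 0.99 / (2 * 20000)))
})
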