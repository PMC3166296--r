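# in-code fixtures shared by the test files; nothing is stored on disk

# dataset with one sample per (tissue, age) condition, values supplied
# tissue-major then age-major as a genes x conditions matrix
pooled_dataset <- function(values, tissues, ages, scale = "log2",
                           detection = NULL) {
  grid <- expand.grid(age = ages, tissue = tissues,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = paste0(grid$tissue, "_", grid$age, "M"),
                        tissue = grid$tissue, age = grid$age,
                        stringsAsFactors = FALSE)
  colnames(values) <- samples$sample_id
  if (!is.null(detection)) colnames(detection) <- samples$sample_id
  expression_dataset(values, samples, scale = scale, detection = detection)
}

# a PhaseChangeSet built from plain arguments, for network-level tests
pcs <- function(tissue, age_from, age_to, direction, genes, unit = "M") {
  phase_change_set(age_phase(tissue, age_from, age_to, unit = unit),
                   direction, genes)
}

# split a build_change_sets() result into per-phase lists
split_by_phase <- function(sets) {
  labels <- vapply(sets, function(s) s$phase$label, "")
  lapply(split(seq_along(sets), labels)[unique(labels)],
         function(idx) sets[idx])
}

# direct-summation tail probability for small universes; intentionally the
# naive combinatorial formula, independent of the package's log-space path
enumeration_tail_p <- function(N, M, K, x) {
  if (x <= 0) return(1)
  i <- x:min(M, K)
  sum(choose(M, i) * choose(N - M, K - i)) / choose(N, K)
}
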