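#' Define an age phase within one tissue
#'
#' An age phase is a comparison window between two ages of one tissue,
#' labelled `"<to><unit>v<from><unit>"` — e.g. ages 4 and 10 months give
#' `"10Mv4M"`. Phase networks use consecutive ages on the dataset ladder;
#' non-adjacent contrasts (such as a 24-vs-4-month endpoint comparison) can
#' be constructed explicitly.
#'
#' @param tissue tissue code used in node names (e.g. `"A"` for adrenal)
#' @param age_from,age_to the two ages compared, `age_from < age_to`
#' @param unit single-character age unit for labels: `"M"` months, `"D"` days
#' @return an object of class `AgePhase`
#' @export
age_phase <- function(tissue, age_from, age_to, unit = "M") {
  stopifnot(is.character(tissue), length(tissue) == 1L, nzchar(tissue),
            is.numeric(age_from), is.numeric(age_to))
  if (grepl("_", tissue, fixed = TRUE))
    stop("tissue codes must not contain '_' (reserved in node names)")
  if (!(age_from < age_to)) stop("age_from must be strictly less than age_to")
  label <- paste0(format_age(age_to), unit, "v", format_age(age_from), unit)
  structure(list(tissue = tissue, age_from = age_from, age_to = age_to,
                 unit = unit, label = label),
            class = "AgePhase")
}

#' Specify a change-detection criterion
#'
#' Exactly one `kind` is active per detection run:
#' * `fold_change` — absolute fold-change of at least `fc_threshold`
#'   (inclusive), i.e. `|log2 difference| >= log2(fc_threshold)` on log2 data.
#' * `z_test` — one-sided two-sample Z test on replicated conditions at level
#'   `z_alpha` per tail.
#' * `mas5_composite` — externally supplied change p-values below
#'   `change_p_threshold` (increase; `1 - p` for decrease), fold-change of at
#'   least `fc_threshold`, and (optionally) both compared conditions detected
#'   Present.
#' * `consensus` — fold-change passed in the same direction in two datasets.
#'
#' @param kind one of `"fold_change"`, `"z_test"`, `"mas5_composite"`,
#'   `"consensus"`
#' @param fc_threshold fold-change ratio, `>= 1`; default 2
#' @param z_alpha per-tail significance level for the Z test; 0.01 suits
#'   replicated natural-aging designs, 0.001 the anti-aging designs
#' @param change_p_threshold level for the composite change p-value filter
#' @param require_presence require Present detection calls in the composite
#'   criterion (skipped with a warning when the dataset has no calls)
#' @return an object of class `ChangeCriterion`
#' @export
change_criterion <- function(kind = c("fold_change", "z_test",
                                      "mas5_composite", "consensus"),
                             fc_threshold = 2, z_alpha = 0.01,
                             change_p_threshold = 0.0025,
                             require_presence = TRUE) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(fc_threshold), fc_threshold >= 1,
            is.numeric(z_alpha), z_alpha > 0, z_alpha < 1,
            is.numeric(change_p_threshold), change_p_threshold > 0,
            change_p_threshold < 1,
            is.logical(require_presence))
  structure(list(kind = kind, fc_threshold = fc_threshold, z_alpha = z_alpha,
                 change_p_threshold = change_p_threshold,
                 require_presence = require_presence),
            class = "ChangeCriterion")
}

#' Directional changed-gene set for one tissue and age phase
#'
#' A `PhaseChangeSet` is a node of the association networks: the set of genes
#' called changed in one direction, in one tissue, over one age phase. Its
#' `node_name` follows the `"<TissueCode>_<phaseLabel>_<direction>"`
#' convention, e.g. `"A_10Mv4M_up"`.
#'
#' @param phase an [age_phase()]
#' @param direction `"up"` or `"down"`
#' @param genes character vector of gene identifiers (deduplicated)
#' @return an object of class `PhaseChangeSet`
#' @export
phase_change_set <- function(phase, direction = c("up", "down"), genes) {
  stopifnot(inherits(phase, "AgePhase"))
  direction <- match.arg(direction)
  genes <- unique(as.character(genes))
  structure(list(phase = phase, direction = direction, genes = genes,
                 node_name = paste(phase$tissue, phase$label, direction,
                                   sep = "_")),
            class = "PhaseChangeSet")
}

#' @export
print.PhaseChangeSet <- function(x, ...) {
  cat(sprintf("PhaseChangeSet %s: %d genes\n", x$node_name, length(x$genes)))
  invisible(x)
}

# columns of the value matrix belonging to one (tissue, age) condition
condition_columns <- function(ds, tissue, age) {
  idx <- which(ds$samples$tissue == tissue & ds$samples$age == age)
  if (!length(idx))
    stop(sprintf("no samples for tissue '%s' at age %s", tissue,
                 format_age(age)))
  idx
}

# per-gene mean over replicates of one condition, NA when nothing measured
condition_means <- function(ds, tissue, age) {
  m <- rowMeans(ds$values[, condition_columns(ds, tissue, age), drop = FALSE],
                na.rm = TRUE)
  m[is.nan(m)] <- NA_real_
  m
}

check_phase_in_dataset <- function(ds, phase) {
  if (!phase$tissue %in% ds$samples$tissue)
    stop("phase references tissue absent from dataset: ", phase$tissue)
  ladder <- age_ladder(ds)
  for (a in c(phase$age_from, phase$age_to)) {
    if (!any(ladder == a))
      stop("phase references age absent from dataset: ", format_age(a))
  }
}

# directional fold-change calls on condition means; named logical vectors
fold_change_calls <- function(ds, phase, fc_threshold) {
  v_from <- condition_means(ds, phase$tissue, phase$age_from)
  v_to <- condition_means(ds, phase$tissue, phase$age_to)
  if (ds$scale == "log2") {
    delta <- v_to - v_from
    thr <- log2(fc_threshold)
    up <- !is.na(delta) & delta >= thr
    down <- !is.na(delta) & delta <= -thr
  } else {
    ok <- !is.na(v_from) & !is.na(v_to) & v_from > 0 & v_to > 0
    ratio <- ifelse(ok, v_to / v_from, NA_real_)
    up <- ok & ratio >= fc_threshold
    down <- ok & ratio <= 1 / fc_threshold
  }
  list(up = up, down = down)
}

#' Call directional changes by fold-change over one age phase
#'
#' Replicates of a condition are aggregated by their arithmetic mean on the
#' stored scale. On log2 data a gene is called up when the log2 difference
#' `age_to - age_from` is at least `log2(fc_threshold)` (inclusive), down
#' when at most the negative of it; on linear data the ratio rule
#' `>= fc_threshold` / `<= 1/fc_threshold` is used. Genes with a missing
#' value at either age are in neither set.
#'
#' @param ds an `ExpressionDataset` with its scale flag set
#' @param phase an [age_phase()]
#' @param criterion a [change_criterion()] supplying `fc_threshold`
#' @return list with elements `up` and `down`, each a [phase_change_set()]
#' @export
detect_fold_change <- function(ds, phase,
                               criterion = change_criterion("fold_change")) {
  stopifnot(inherits(ds, "ExpressionDataset"), inherits(phase, "AgePhase"))
  check_phase_in_dataset(ds, phase)
  calls <- fold_change_calls(ds, phase, criterion$fc_threshold)
  list(up = phase_change_set(phase, "up", rownames(ds$values)[calls$up]),
       down = phase_change_set(phase, "down", rownames(ds$values)[calls$down]))
}

#' Call directional changes by a one-sided two-sample Z test
#'
#' For each gene, `z = (mean_to - mean_from) / sqrt(s2_to/n_to +
#' s2_from/n_from)` with unpooled per-group sample variances (`n - 1`
#' denominators). A gene is called up when the upper-tail standard-normal
#' probability is below `z_alpha`, down when the lower tail is. Genes with
#' fewer than two non-missing replicates in either condition, or with a zero
#' standard error, are skipped; skip counts are attached as the `"skipped"`
#' attribute of the result.
#'
#' @inheritParams detect_fold_change
#' @param criterion a [change_criterion()] supplying `z_alpha`
#' @return list with elements `up` and `down` ([phase_change_set()]s);
#'   attribute `skipped` holds counts `too_few_replicates` and
#'   `zero_variance`
#' @export
detect_z_test <- function(ds, phase, criterion = change_criterion("z_test")) {
  stopifnot(inherits(ds, "ExpressionDataset"), inherits(phase, "AgePhase"))
  check_phase_in_dataset(ds, phase)
  x_from <- ds$values[, condition_columns(ds, phase$tissue, phase$age_from),
                      drop = FALSE]
  x_to <- ds$values[, condition_columns(ds, phase$tissue, phase$age_to),
                    drop = FALSE]
  n1 <- rowSums(!is.na(x_from))
  n2 <- rowSums(!is.na(x_to))
  enough <- n1 >= 2 & n2 >= 2
  m1 <- rowMeans(x_from, na.rm = TRUE)
  m2 <- rowMeans(x_to, na.rm = TRUE)
  v1 <- (rowSums(x_from^2, na.rm = TRUE) - n1 * m1^2) / pmax(n1 - 1, 1)
  v2 <- (rowSums(x_to^2, na.rm = TRUE) - n2 * m2^2) / pmax(n2 - 1, 1)
  v1 <- pmax(v1, 0)  # guard tiny negative values from cancellation
  v2 <- pmax(v2, 0)
  se <- sqrt(v1 / n1 + v2 / n2)
  degenerate <- enough & se == 0
  usable <- enough & se > 0
  z <- ifelse(usable, (m2 - m1) / se, NA_real_)
  up <- usable & stats::pnorm(z, lower.tail = FALSE) < criterion$z_alpha
  down <- usable & stats::pnorm(z) < criterion$z_alpha
  skipped <- c(too_few_replicates = sum(!enough),
               zero_variance = sum(degenerate))
  if (sum(skipped) > 0)
    message(sprintf(
      "detect_z_test [%s %s]: skipped %d gene(s) with <2 replicates, %d with zero variance",
      phase$tissue, phase$label, skipped[["too_few_replicates"]],
      skipped[["zero_variance"]]))
  out <- list(up = phase_change_set(phase, "up", rownames(ds$values)[up]),
              down = phase_change_set(phase, "down", rownames(ds$values)[down]))
  attr(out, "skipped") <- skipped
  out
}

#' Call directional changes by the MAS5-style composite criterion
#'
#' Combines three filters for pooled-sample Affymetrix designs: an externally
#' supplied per-gene change p-value below `change_p_threshold` for an
#' increase (`1 - p` below it for a decrease), an absolute fold-change of at
#' least `fc_threshold`, and — when detection calls are available — every
#' sample of both compared conditions detected Present. Change p-values come
#' from the array-processing software and are consumed, never computed here.
#'
#' @inheritParams detect_fold_change
#' @param change_p named numeric vector of change p-values for this
#'   comparison, one per gene of `ds`
#' @param detection optional calls matrix overriding `ds$detection`
#' @return list with elements `up` and `down` ([phase_change_set()]s)
#' @export
detect_mas5_composite <- function(ds, phase,
                                  criterion = change_criterion("mas5_composite"),
                                  change_p, detection = NULL) {
  stopifnot(inherits(ds, "ExpressionDataset"), inherits(phase, "AgePhase"))
  check_phase_in_dataset(ds, phase)
  if (missing(change_p) || is.null(change_p))
    stop("the mas5_composite criterion needs a change_p table")
  genes <- rownames(ds$values)
  if (!is.null(names(change_p))) {
    cp <- unname(change_p[genes])
  } else {
    stopifnot(length(change_p) == length(genes))
    cp <- as.numeric(change_p)
  }

  fc <- fold_change_calls(ds, phase, criterion$fc_threshold)

  detection <- detection %||% ds$detection
  if (criterion$require_presence && is.null(detection)) {
    warning("no detection calls available; presence filter skipped")
    present <- rep(TRUE, length(genes))
  } else if (criterion$require_presence) {
    cols <- c(condition_columns(ds, phase$tissue, phase$age_from),
              condition_columns(ds, phase$tissue, phase$age_to))
    d <- detection[, cols, drop = FALSE]
    present <- rowSums(d == "P", na.rm = TRUE) == ncol(d)
  } else {
    present <- rep(TRUE, length(genes))
  }

  thr <- criterion$change_p_threshold
  up <- !is.na(cp) & cp < thr & fc$up & present
  down <- !is.na(cp) & (1 - cp) < thr & fc$down & present
  list(up = phase_change_set(phase, "up", genes[up]),
       down = phase_change_set(phase, "down", genes[down]))
}

#' Call directional changes shared by two datasets (consensus)
#'
#' For designs measured twice (two arrays of the same aging process), a gene
#' is called only when it passes the fold-change rule in the same direction
#' in both datasets. Gene universes are intersected; any loss is reported.
#'
#' @param ds_a,ds_b two `ExpressionDataset`s sharing the age ladder
#' @inheritParams detect_fold_change
#' @return list with elements `up` and `down` ([phase_change_set()]s)
#' @export
detect_consensus <- function(ds_a, ds_b, phase,
                             criterion = change_criterion("consensus")) {
  stopifnot(inherits(ds_a, "ExpressionDataset"),
            inherits(ds_b, "ExpressionDataset"))
  common <- intersect(rownames(ds_a$values), rownames(ds_b$values))
  lost <- length(rownames(ds_a$values)) + length(rownames(ds_b$values)) -
    2L * length(common)
  if (lost > 0)
    message(sprintf("detect_consensus: restricting to %d shared genes (%d dropped)",
                    length(common), lost))
  ds_a <- subset_genes(ds_a, match(common, rownames(ds_a$values)))
  ds_b <- subset_genes(ds_b, match(common, rownames(ds_b$values)))
  check_phase_in_dataset(ds_a, phase)
  check_phase_in_dataset(ds_b, phase)
  a <- fold_change_calls(ds_a, phase, criterion$fc_threshold)
  b <- fold_change_calls(ds_b, phase, criterion$fc_threshold)
  list(up = phase_change_set(phase, "up", common[a$up & b$up]),
       down = phase_change_set(phase, "down", common[a$down & b$down]))
}

#' Build all directional change sets of a dataset
#'
#' Runs the configured criterion for every tissue over every consecutive age
#' phase, yielding `2 x tissues x phases` sets (some possibly empty), named
#' by the `"<TissueCode>_<phaseLabel>_<direction>"` convention. These are the
#' nodes of the association networks.
#'
#' @param ds an `ExpressionDataset`
#' @param criterion a [change_criterion()] of kind `fold_change`, `z_test` or
#'   `mas5_composite` (`consensus` needs two datasets — use
#'   [detect_consensus()] directly)
#' @param unit age unit used in phase labels
#' @param include_endpoint also add the non-adjacent first-vs-last age
#'   contrast for each tissue (off by default; the phase networks use
#'   consecutive phases only)
#' @param change_p for `mas5_composite`: nested list
#'   `change_p[[tissue]][[phase_label]]` of per-gene change p-value vectors
#' @return named list of [phase_change_set()]s, ordered tissue-major,
#'   then phase, then up before down
#' @export
build_change_sets <- function(ds, criterion = change_criterion("fold_change"),
                              unit = "M", include_endpoint = FALSE,
                              change_p = NULL) {
  stopifnot(inherits(ds, "ExpressionDataset"),
            inherits(criterion, "ChangeCriterion"))
  tissues <- unique(ds$samples$tissue)
  ladder <- age_ladder(ds)
  if (length(ladder) < 2 || nrow(ds$values) == 0) return(list())
  phase_ages <- Map(c, ladder[-length(ladder)], ladder[-1])
  if (include_endpoint && length(ladder) > 2)
    phase_ages <- c(phase_ages, list(c(ladder[1], ladder[length(ladder)])))

  sets <- list()
  for (tissue in tissues) {
    for (pa in phase_ages) {
      phase <- age_phase(tissue, pa[1], pa[2], unit = unit)
      res <- switch(criterion$kind,
        fold_change = detect_fold_change(ds, phase, criterion),
        z_test = detect_z_test(ds, phase, criterion),
        mas5_composite = detect_mas5_composite(
          ds, phase, criterion,
          change_p = change_p[[tissue]][[phase$label]]),
        consensus = stop(
          "consensus detection needs two datasets; use detect_consensus()"))
      sets[[res$up$node_name]] <- res$up
      sets[[res$down$node_name]] <- res$down
    }
  }
  sets
}
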