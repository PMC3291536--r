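# Microarray knockdown analysis: the fold-change/t-test probe filter, the
# cluster-analysis prefilter, Venn overlaps between regulated gene sets, and
# group-mean expression changes per occupancy category.

#' Fold-change and t-test differential expression filter
#'
#' Per probe: group means, fold change `mean_test / mean_control`, and a
#' two-tailed t-test between the replicate groups (equal-variance by default,
#' the spreadsheet-era convention). A probe passes when the fold change is
#' strictly beyond `fold` in the selected direction and `p < alpha` (both
#' strict). A zero control mean leaves the fold undefined and the probe not
#' passed (flagged).
#'
#' @param mat numeric probe x sample matrix.
#' @param groups named list of sample name vectors (>= 2 replicates each).
#' @param control,test group names to compare.
#' @param fold fold-change cutoff (strictly greater).
#' @param alpha p-value cutoff (strictly below).
#' @param direction `"up"` (fold > `fold`), `"down"` (fold < 1/`fold`) or
#'   `"both"`.
#' @param var_equal equal-variance t-test (TRUE) or Welch (FALSE).
#' @return data frame: probe_id, mean_control, mean_test, fold, p_value,
#'   pass, undefined_fold.
#' @export
de_filter <- function(mat, groups, control = "control", test,
                      fold = 2, alpha = 0.05,
                      direction = c("up", "down", "both"), var_equal = TRUE) {
  direction <- match.arg(direction)
  .check_groups(groups, colnames(mat))
  xc <- mat[, groups[[control]], drop = FALSE]
  xt <- mat[, groups[[test]], drop = FALSE]
  mc <- rowMeans(xc); mt <- rowMeans(xt)
  fc <- ifelse(mc > 0, mt / mc, NA_real_)
  p <- vapply(seq_len(nrow(mat)), function(i) {
    if (stats::sd(xc[i, ]) == 0 && stats::sd(xt[i, ]) == 0)
      return(if (mc[i] == mt[i]) 1 else 0)   # constant replicates: degenerate t
    stats::t.test(xt[i, ], xc[i, ], var.equal = var_equal)$p.value
  }, numeric(1))
  hit <- switch(direction,
                up = fc > fold,
                down = fc < 1 / fold,
                both = fc > fold | fc < 1 / fold)
  pass <- !is.na(fc) & hit & p < alpha
  data.frame(probe_id = rownames(mat) %||% as.character(seq_len(nrow(mat))),
             mean_control = mc, mean_test = mt, fold = fc, p_value = p,
             pass = pass, undefined_fold = is.na(fc),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Venn partition counts of two id sets
#'
#' @param set_a,set_b character vectors of probe or gene ids.
#' @return named integer vector `(a_only, both, b_only)`.
#' @export
venn_counts <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  both <- length(intersect(a, b))
  c(a_only = length(a) - both, both = both, b_only = length(b) - both)
}

#' Variation prefilter used before cluster analysis
#'
#' Keeps probes with 1) at least one array reading above `min_read` and
#' 2) more than one array deviating at least `dev_fold`-fold from the probe's
#' mean (in either direction).
#'
#' @param mat numeric probe x sample matrix.
#' @param min_read minimum max-array reading (strictly above).
#' @param dev_fold deviation fold relative to the probe mean.
#' @param min_dev_arrays minimum number of deviating arrays (at least).
#' @return data frame: probe_id, max_value, n_deviating, keep.
#' @export
cluster_prefilter <- function(mat, min_read = 10, dev_fold = 1.5,
                              min_dev_arrays = 2) {
  mx <- apply(mat, 1, max)
  m <- rowMeans(mat)
  dev <- mat / m
  ndev <- rowSums(dev >= dev_fold | dev <= 1 / dev_fold)
  ndev[m == 0] <- 0
  data.frame(probe_id = rownames(mat) %||% as.character(seq_len(nrow(mat))),
             max_value = mx, n_deviating = ndev,
             keep = mx > min_read & ndev >= min_dev_arrays,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Mean expression change per occupancy category
#'
#' Summarizes per-gene log2 expression changes within categories (e.g. PcG
#' gain / loss / unchanged at the bound sites): mean, standard error of the
#' mean, and pairwise two-tailed Student's t-tests between categories.
#' Categories of size one get an `NA` SEM and are flagged.
#'
#' @param changes numeric vector of per-gene log2 expression changes.
#' @param categories character vector parallel to `changes`.
#' @param var_equal equal-variance t-tests (default TRUE).
#' @return list with `summary` (category, n, mean, sem, degenerate) and
#'   `pairwise_p` (symmetric matrix of p-values).
#' @export
expression_by_category <- function(changes, categories, var_equal = TRUE) {
  stopifnot(length(changes) == length(categories))
  cats <- sort(unique(categories))
  summ <- data.frame(
    category = cats,
    n = as.integer(tapply(changes, categories, length)[cats]),
    mean = as.numeric(tapply(changes, categories, mean)[cats]),
    sem = as.numeric(tapply(changes, categories, function(v)
      if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_)[cats]),
    stringsAsFactors = FALSE, row.names = NULL)
  summ$degenerate <- summ$n < 2
  pw <- matrix(NA_real_, length(cats), length(cats),
               dimnames = list(cats, cats))
  if (length(cats) > 1)
    for (i in seq_along(cats)) for (j in seq_along(cats)) {
      if (i >= j) next
      vi <- changes[categories == cats[i]]
      vj <- changes[categories == cats[j]]
      if (length(vi) > 1 && length(vj) > 1)
        pw[i, j] <- pw[j, i] <-
          stats::t.test(vi, vj, var.equal = var_equal)$p.value
    }
  list(summary = summ, pairwise_p = pw)
}
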