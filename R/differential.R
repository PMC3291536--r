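# The per-peak signal table is the pipeline's central object: depth-scaled
# counts per factor x genotype, ratios, gain/loss classes, positivity flags,
# TSS distance and CpG stratification, one row per peak.

#' Classify a knockout/wild-type count ratio
#'
#' `r = (ko + pseudocount) / (wt + pseudocount)`; a peak is `decreased` when
#' `r <= 1/fold`, `increased` when `r >= fold`, otherwise `unchanged`. The
#' boundary (exactly `fold`-fold) counts as changed, and the pseudocount makes
#' the 0/0 case a ratio of 1.
#'
#' @param wt,ko non-negative counts (vectors allowed).
#' @param pseudocount added to both counts.
#' @param fold fold-change cutoff (> 1).
#' @return list with `ratio` and `class` (character vector in
#'   `c("decreased", "unchanged", "increased")`).
#' @export
classify_ratio <- function(wt, ko, pseudocount = 1, fold = 1.5) {
  stopifnot(fold > 1, all(wt >= 0), all(ko >= 0))
  r <- (ko + pseudocount) / (wt + pseudocount)
  cls <- ifelse(r <= 1 / fold, "decreased",
                ifelse(r >= fold, "increased", "unchanged"))
  list(ratio = r, class = cls)
}

#' Build the per-peak signal table
#'
#' Quantifies every supplied track at every peak: the raw tag count within the
#' peak interval and the mean reads/Kb in the +/- `flank` window, both
#' depth-scaled to the smallest library among the quantified tracks
#' (`N_min / N_sample`), since the positivity threshold is stated in reads.
#' For each factor with both genotypes present, the knockout/wild-type ratio
#' over the peak interval is classified at `fold` and a positivity flag
#' records whether reads/Kb exceeds `positivity_threshold` in either genotype.
#'
#' @param peaks interval data frame with `id`.
#' @param tracks named list of [tag_track()] objects; names are
#'   `"<factor>_<genotype>"` (e.g. `"rnf2_wt"`). IgG tracks are not quantified
#'   here.
#' @param genes optional gene table; adds `tss_distance` and `nearest_gene`.
#' @param islands optional CpG island intervals; adds `cpg_distance`,
#'   `cpg_gap`, `cpg_label`.
#' @param genotypes the two genotype labels, wild-type first.
#' @param flank positivity window half-width in bp.
#' @param positivity_threshold reads/Kb cutoff (exceeded strictly).
#' @param pseudocount,fold passed to [classify_ratio()].
#' @return a `data.frame` of class `peak_signal_table`; per factor `f` it
#'   carries `f_<gt>_count`, `f_<gt>_rpkb`, `f_ratio`, `f_class`, `f_positive`.
#' @export
peak_signal_table <- function(peaks, tracks, genes = NULL, islands = NULL,
                              genotypes = c("wt", "ko"), flank = 1000,
                              positivity_threshold = 5, pseudocount = 1,
                              fold = 1.5) {
  .check_intervals(peaks, "peaks")
  if (is.null(peaks$id)) peaks$id <- as.character(seq_len(nrow(peaks)))
  out <- data.frame(peak_id = peaks$id, chrom = peaks$chrom,
                    start = peaks$start, end = peaks$end,
                    stringsAsFactors = FALSE)
  if (!is.null(genes)) {
    nt <- nearest_tss(peaks, genes)
    out$tss_distance <- nt$distance
    out$nearest_gene <- nt$gene_id
  }
  if (!is.null(islands)) {
    cg <- cpg_distance(peaks, islands)
    out$cpg_distance <- cg$distance
    out$cpg_gap <- cg$gap
    out$cpg_label <- cg$label
  }
  n_min <- min(vapply(tracks, `[[`, numeric(1), "library_size"))
  width <- peaks$end - peaks$start
  for (nm in names(tracks)) {
    tr <- tracks[[nm]]
    scale <- n_min / tr$library_size
    # count within the called peak interval itself (used for the ratio key)
    cnt <- vapply(seq_len(nrow(peaks)), function(i)
      .count_range(tr$tags[[peaks$chrom[i]]], peaks$start[i], peaks$end[i]),
      numeric(1))
    out[[paste0(nm, "_count")]] <- cnt * scale
    out[[paste0(nm, "_rpkb")]] <- mean_reads_per_kb(tr, peaks, flank) * scale
  }
  factors <- unique(sub(paste0("_(", paste(genotypes, collapse = "|"), ")$"),
                        "", names(tracks)))
  wt <- genotypes[1]; ko <- genotypes[2]
  for (f in factors) {
    cw <- out[[paste0(f, "_", wt, "_count")]]
    ck <- out[[paste0(f, "_", ko, "_count")]]
    if (is.null(cw) || is.null(ck)) next
    cl <- classify_ratio(cw, ck, pseudocount = pseudocount, fold = fold)
    out[[paste0(f, "_ratio")]] <- cl$ratio
    out[[paste0(f, "_class")]] <- cl$class
    out[[paste0(f, "_positive")]] <-
      out[[paste0(f, "_", wt, "_rpkb")]] > positivity_threshold |
      out[[paste0(f, "_", ko, "_rpkb")]] > positivity_threshold
  }
  class(out) <- c("peak_signal_table", "data.frame")
  attr(out, "genotypes") <- genotypes
  attr(out, "positivity_threshold") <- positivity_threshold
  attr(out, "fold") <- fold
  out
}

#' Keep peaks with appreciable signal for a factor
#'
#' Retains peaks whose mean reads/Kb exceeds `threshold` (strictly) in either
#' genotype — the "very low or no signal" rows are dropped before ratio
#' analyses.
#'
#' @param table a [peak_signal_table()].
#' @param factor factor name, e.g. `"rnf2"`.
#' @param threshold reads/Kb cutoff.
#' @return the filtered table.
#' @export
positivity_filter <- function(table, factor, threshold = 5) {
  gts <- attr(table, "genotypes") %||% c("wt", "ko")
  cols <- paste0(factor, "_", gts, "_rpkb")
  if (!all(cols %in% names(table)))
    stop("unknown factor: ", factor)
  keep <- table[[cols[1]]] > threshold | table[[cols[2]]] > threshold
  table[keep, , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Chi-squared enrichment of signal changes at peaks vs matched controls
#'
#' Builds the 2x2 table (changed vs not) x (peaks vs controls) and applies
#' Pearson's chi-squared test without continuity correction (df = 1).
#' `direction` selects which class counts as changed.
#'
#' @param peak_classes,control_classes character vectors of classes from
#'   [classify_ratio()] (any values; only matches to `direction` count), or
#'   logical vectors of the changed indicator.
#' @param direction `"decreased"`, `"increased"`, or `"positive"`-style custom
#'   label matched against the class vectors; logical inputs ignore it.
#' @return object of class `enrichment_test`: list with `table`, `statistic`,
#'   `df`, `p_value`, `direction`, `degenerate` (TRUE when a margin is zero,
#'   in which case statistic and p are `NA`).
#' @export
chi2_enrichment <- function(peak_classes, control_classes,
                            direction = "decreased") {
  as_changed <- function(x) if (is.logical(x)) x else x == direction
  pc <- as_changed(peak_classes); cc <- as_changed(control_classes)
  tab <- rbind(peaks = c(changed = sum(pc), other = sum(!pc)),
               controls = c(changed = sum(cc), other = sum(!cc)))
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  if (degenerate) {
    stat <- NA_real_; p <- NA_real_
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    stat <- unname(ct$statistic); p <- ct$p.value
  }
  structure(list(table = tab, statistic = stat, df = 1L, p_value = p,
                 direction = direction, degenerate = degenerate),
            class = "enrichment_test")
}

#' @export
print.enrichment_test <- function(x, ...) {
  cat("<enrichment_test> direction:", x$direction, "\n")
  print(x$table)
  if (x$degenerate) cat("  degenerate margin; chi-squared undefined\n")
  else cat(sprintf("  X-squared = %.4g, df = 1, p = %.4g\n",
                   x$statistic, x$p_value))
  invisible(x)
}

#' Split peaks into low/high signal groups for a factor
#'
#' Partitions the (already positivity-filtered) table by the wild-type
#' reads/Kb of `group_factor` at `threshold` (strictly greater is high), and
#' returns the paired wild-type/knockout counts of `ratio_factor` per group
#' for scatter plotting, with per-group mean log2 ratios.
#'
#' @param table a [peak_signal_table()].
#' @param group_factor factor whose level defines the groups.
#' @param ratio_factor factor whose wt/ko signal is reported.
#' @param threshold reads/Kb cutoff.
#' @return list with `scatter` (peak_id, group, wt, ko, ratio) and
#'   `group_means` (mean log2 ratio per group).
#' @export
group_by_level <- function(table, group_factor, ratio_factor, threshold = 5) {
  gts <- attr(table, "genotypes") %||% c("wt", "ko")
  lev <- table[[paste0(group_factor, "_", gts[1], "_rpkb")]]
  if (is.null(lev)) stop("unknown factor: ", group_factor)
  grp <- ifelse(lev > threshold, "high", "low")
  wtc <- table[[paste0(ratio_factor, "_", gts[1], "_count")]]
  koc <- table[[paste0(ratio_factor, "_", gts[2], "_count")]]
  r <- table[[paste0(ratio_factor, "_ratio")]]
  scatter <- data.frame(peak_id = table$peak_id, group = grp,
                        wt = wtc, ko = koc, ratio = r,
                        stringsAsFactors = FALSE)
  means <- tapply(log2(r), grp, mean)
  list(scatter = scatter, group_means = means)
}

# Geometric bin index: k = floor(log(v / anchor) / log(fold)); the anchor is
# 1 read/Kb for signals and 1 Kb for distances.
.geom_bin <- function(v, fold, anchor) {
  k <- rep(NA_integer_, length(v))
  pos <- which(is.finite(v) & v > 0)
  k[pos] <- as.integer(floor(log(v[pos] / anchor) / log(fold) + 1e-9))
  k
}

#' Two-parameter binned density grid of signal changes
#'
#' Bins peaks on two axes — a signal (geometric 1.5-fold bins of reads/Kb) or
#' an absolute distance (geometric 2-fold bins of bp) — and reports per-bin
#' peak counts and mean log2 knockout/wild-type ratio for `ratio_factor`,
#' plus marginal histograms and a Welch (unequal-variance, two-tailed) t-test
#' between two designated groups of x-bins (default: the lowest vs the highest
#' occupied x-bin).
#'
#' An axis spec is a list: `list(type = "signal", factor = "suz12",
#' genotype = "wt", fold = 1.5)` or `list(type = "distance",
#' column = "tss_distance", fold = 2)`. Peaks with infinite distance (no
#' feature on the chromosome) are routed to an overflow bin; zero or missing
#' values to an underflow bin.
#'
#' @param table a [peak_signal_table()].
#' @param x_spec,y_spec axis specifications (see above).
#' @param ratio_factor factor whose log2 ratio colors the grid.
#' @param welch_groups optional list of two vectors of x-bin indices to
#'   compare.
#' @return object of class `density_grid`: `cells` (x_bin, y_bin, count,
#'   mean_log2_ratio), `x_marginal`, `y_marginal`, `welch` (htest or NULL),
#'   `n`.
#' @export
density_grid <- function(table, x_spec, y_spec, ratio_factor,
                         welch_groups = NULL) {
  gts <- attr(table, "genotypes") %||% c("wt", "ko")
  axis_values <- function(spec) {
    if (spec$type == "signal") {
      col <- paste0(spec$factor, "_", spec$genotype %||% gts[1], "_rpkb")
      v <- table[[col]]
      if (is.null(v)) stop("unknown signal column: ", col)
      list(v = v, fold = spec$fold %||% 1.5, anchor = 1)
    } else if (spec$type == "distance") {
      v <- abs(table[[spec$column]])
      if (is.null(v)) stop("unknown distance column: ", spec$column)
      list(v = v, fold = spec$fold %||% 2, anchor = 1000)
    } else stop("axis type must be 'signal' or 'distance'")
  }
  ax <- axis_values(x_spec); ay <- axis_values(y_spec)
  bin_axis <- function(a) {
    k <- .geom_bin(a$v, a$fold, a$anchor)
    k[is.finite(a$v) & a$v == 0] <- -1000L       # underflow
    k[!is.finite(a$v)] <- 1000L                  # overflow (Inf sentinel)
    k
  }
  xb <- bin_axis(ax); yb <- bin_axis(ay)
  lr <- log2(table[[paste0(ratio_factor, "_ratio")]])
  if (is.null(lr)) stop("unknown ratio factor: ", ratio_factor)
  key <- interaction(xb, yb, drop = TRUE)
  cells <- data.frame(
    x_bin = as.integer(tapply(xb, key, `[`, 1)),
    y_bin = as.integer(tapply(yb, key, `[`, 1)),
    count = as.integer(tapply(lr, key, length)),
    mean_log2_ratio = as.numeric(tapply(lr, key, mean)))
  cells <- cells[order(cells$x_bin, cells$y_bin), , drop = FALSE]
  xm <- as.data.frame(table(x_bin = xb), stringsAsFactors = FALSE)
  ym <- as.data.frame(table(y_bin = yb), stringsAsFactors = FALSE)
  xm$x_bin <- as.integer(xm$x_bin); ym$y_bin <- as.integer(ym$y_bin)
  names(xm)[2] <- "count"; names(ym)[2] <- "count"
  if (is.null(welch_groups)) {
    occ <- sort(unique(xb[abs(xb) < 1000]))
    welch_groups <- if (length(occ) >= 2)
      list(min(occ), max(occ)) else NULL
  }
  welch <- NULL
  if (!is.null(welch_groups)) {
    g1 <- lr[xb %in% welch_groups[[1]]]
    g2 <- lr[xb %in% welch_groups[[2]]]
    if (length(g1) >= 2 && length(g2) >= 2)
      welch <- tryCatch(stats::t.test(g1, g2, var.equal = FALSE),
                        error = function(e) NULL)   # constant data, etc.
  }
  structure(list(cells = cells, x_marginal = xm, y_marginal = ym,
                 welch = welch, n = nrow(table)),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat("<density_grid>", x$n, "peaks in", nrow(x$cells), "occupied cells\n")
  if (!is.null(x$welch))
    cat(sprintf("  Welch t between designated x-bin groups: p = %.3g\n",
                x$welch$p.value))
  invisible(x)
}

#' Squared Pearson correlation of the signal change with a parameter
#'
#' Correlates `log(ratio)` with `log(parameter)` over the peaks in the table
#' (both log-transformed; non-positive parameter values are lifted by a
#' pseudocount) and returns r-squared.
#'
#' @param table a [peak_signal_table()].
#' @param ratio_factor factor whose ratio is the response.
#' @param parameter column name of the parameter (distances are used as
#'   absolute values).
#' @param pseudocount added to the parameter before the log when any value is
#'   `<= 0`.
#' @return list with `r2`, `r`, `n`.
#' @export
correlate_change <- function(table, ratio_factor, parameter, pseudocount = 1) {
  r <- table[[paste0(ratio_factor, "_ratio")]]
  if (is.null(r)) stop("unknown ratio factor: ", ratio_factor)
  p <- table[[parameter]]
  if (is.null(p)) stop("unknown parameter column: ", parameter)
  p <- abs(p)
  keep <- is.finite(r) & is.finite(p)
  r <- r[keep]; p <- p[keep]
  if (any(p <= 0)) p <- p + pseudocount
  cc <- stats::cor(log(r), log(p))
  list(r2 = cc^2, r = cc, n = length(r))
}
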