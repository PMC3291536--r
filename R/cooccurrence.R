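# Observed/expected co-occurrence of two peak sets over strand-oriented
# positions around gene anchors (TSS or TE). The per-gene indicator reduces
# every cell to a Bernoulli count, so the expected frequency model and the
# binomial test fall out directly.

#' Per-gene peak presence indicators along anchored offsets
#'
#' For each gene and each scan offset `k`, records whether some peak center
#' lies within `[anchor(g) + k - w/2, anchor(g) + k + w/2)` in strand-oriented
#' coordinates (offsets count along the direction of transcription, so the
#' pattern of a `-` strand gene is the mirror of the `+` strand case).
#'
#' @param peaks interval data frame (peak centers are used).
#' @param genes gene model table.
#' @param anchor `"tss"` or `"te"`.
#' @param offsets scan offsets in bp (default every 500 bp across +/- 20 Kb).
#' @param window scan window width in bp (2,500 by default).
#' @return logical matrix, genes x offsets, dimnames set.
#' @export
gene_offset_indicators <- function(peaks, genes, anchor = c("tss", "te"),
                                   offsets = seq(-20000, 20000, by = 500),
                                   window = 2500) {
  anchor <- match.arg(anchor)
  .check_intervals(peaks, "peaks")
  .check_genes(genes)
  ctr <- interval_center(peaks)
  centers_by_chrom <- split(ctr, peaks$chrom)
  centers_by_chrom <- lapply(centers_by_chrom, sort)
  half <- window / 2
  m <- matrix(FALSE, nrow = nrow(genes), ncol = length(offsets),
              dimnames = list(genes$gene_id, as.character(offsets)))
  for (i in seq_len(nrow(genes))) {
    pos <- centers_by_chrom[[genes$chrom[i]]]
    if (is.null(pos) || !length(pos)) next
    a <- if (anchor == "tss") genes$tss[i] else genes$te[i]
    # oriented offset of each peak center: downstream of transcription > 0
    off <- if (genes$strand[i] == "+") pos - a else a - pos
    off <- sort(off)
    cnt <- findInterval(offsets + half - 1, off) -
      findInterval(offsets - half - 1, off)
    m[i, ] <- cnt > 0
  }
  m
}

#' Observed/expected co-occurrence matrix of two peak sets
#'
#' For indicator matrices A and B over the same gene universe,
#' `O(i, j)` counts genes carrying an A peak at offset `i` and a B peak at
#' offset `j`; the expectation under independent placement is
#' `E(i, j) = N * f_A(i) * f_B(j)` with `f_X(k)` the marginal per-gene peak
#' frequency. Each cell gets a two-tailed exact binomial p-value for `O`
#' successes in `N` trials at rate `f_A(i) * f_B(j)`; significance is
#' Bonferroni-corrected over the non-masked cells at `alpha`. Cells with a
#' zero marginal frequency are masked.
#'
#' @param ind_a,ind_b logical matrices from [gene_offset_indicators()] with
#'   identical row sets.
#' @param alpha family-wise significance level before correction.
#' @param anchor label stored for provenance (`"tss"`/`"te"`).
#' @param p_values set FALSE to skip the per-cell binomial tests (observed,
#'   expected and ratios only), e.g. inside permutation loops.
#' @return object of class `cooccurrence_matrix`: `observed`, `expected`,
#'   `log2_ratio`, `p_value`, `significant`, `masked` matrices plus `n_genes`,
#'   `offsets_a`, `offsets_b`, `bonferroni_cells`.
#' @export
cooccurrence_matrix <- function(ind_a, ind_b, alpha = 0.05, anchor = NA,
                                p_values = TRUE) {
  if (!identical(rownames(ind_a), rownames(ind_b)))
    stop("indicator matrices must share the same gene universe")
  n <- nrow(ind_a)
  O <- crossprod(ind_a, ind_b)            # offsets_a x offsets_b
  fa <- colMeans(ind_a); fb <- colMeans(ind_b)
  E <- n * outer(fa, fb)
  masked <- outer(fa == 0, fb == 0, `|`)
  ratio <- suppressWarnings(log2(O / E))
  ratio[masked] <- NA
  p <- matrix(NA_real_, nrow(O), ncol(O), dimnames = dimnames(O))
  rate <- outer(fa, fb)
  if (p_values)
    for (i in seq_len(nrow(O))) for (j in seq_len(ncol(O))) {
      if (masked[i, j]) next
      p[i, j] <- stats::binom.test(O[i, j], n, rate[i, j])$p.value
    }
  n_cells <- sum(!masked)
  sig <- !masked & !is.na(p) & p < alpha / n_cells
  structure(list(observed = O, expected = E, log2_ratio = ratio,
                 p_value = p, significant = sig, masked = masked,
                 n_genes = n, offsets_a = colnames(ind_a),
                 offsets_b = colnames(ind_b), anchor = anchor,
                 alpha = alpha, bonferroni_cells = n_cells),
            class = "cooccurrence_matrix")
}

#' @export
print.cooccurrence_matrix <- function(x, ...) {
  cat("<cooccurrence_matrix>", nrow(x$observed), "x", ncol(x$observed),
      "cells over", x$n_genes, "genes; anchor:", x$anchor, "\n")
  cat("  significant (Bonferroni", x$alpha, "/", x$bonferroni_cells, "):",
      sum(x$significant, na.rm = TRUE), "cells\n")
  invisible(x)
}

#' Color-code a co-occurrence matrix
#'
#' Cells with more observed than expected co-occurrences are blue, fewer are
#' red, and significant cells get a transparent green overlay; intensity
#' scales with `|log2(O/E)|` up to `saturation`. A pure function of the ratio
#' and significance matrices.
#'
#' @param x a [cooccurrence_matrix()].
#' @param saturation absolute log2 ratio mapping to full intensity.
#' @return array offsets_a x offsets_b x 3 of RGB values in \[0, 1\]; masked
#'   cells are grey.
#' @export
render_matrix <- function(x, saturation = 2) {
  r <- x$log2_ratio
  w <- pmin(abs(r) / saturation, 1)
  w[!is.finite(r)] <- 1                       # O = 0 cells at full depletion
  rgb <- array(1, dim = c(dim(r), 3),
               dimnames = list(rownames(r), colnames(r), c("R", "G", "B")))
  up <- !x$masked & !is.na(r) & r > 0                    # enriched -> blue
  dn <- !x$masked & !is.na(r) & r < 0                    # depleted -> red
  for (k in 1:3) {
    plane <- rgb[, , k]
    if (k != 3) plane[up] <- 1 - w[up]        # blue: drop R and G
    if (k != 1) plane[dn] <- 1 - w[dn]        # red: drop G and B
    rgb[, , k] <- plane
  }
  sig <- which(x$significant & !x$masked)
  for (k in 1:3) {                            # alpha-blend green overlay
    plane <- rgb[, , k]
    plane[sig] <- 0.5 * plane[sig] + 0.5 * (if (k == 2) 1 else 0)
    rgb[, , k] <- plane
  }
  grey <- which(x$masked)
  for (k in 1:3) { plane <- rgb[, , k]; plane[grey] <- 0.8; rgb[, , k] <- plane }
  rgb
}

#' Export a co-occurrence matrix in long format
#'
#' @param x a [cooccurrence_matrix()].
#' @return data frame with anchor, i, j, observed, expected, log2_ratio,
#'   p_value, significant.
#' @export
cooccurrence_table <- function(x) {
  grid <- expand.grid(i = x$offsets_a, j = x$offsets_b,
                      stringsAsFactors = FALSE)
  data.frame(anchor = x$anchor, grid,
             observed = as.vector(x$observed),
             expected = as.vector(x$expected),
             log2_ratio = as.vector(x$log2_ratio),
             p_value = as.vector(x$p_value),
             significant = as.vector(x$significant))
}
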