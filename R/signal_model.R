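# Window counting is binary search on the per-chromosome sorted tag vectors:
# tags in [lo, hi) = #(pos <= hi-1) - #(pos <= lo-1), O(log n) per query.

.count_range <- function(pos, lo, hi) {
  if (is.null(pos) || !length(pos)) return(0L)
  findInterval(hi - 1, pos) - findInterval(lo - 1, pos)
}

#' Count tags in a window around an interval center
#'
#' Counts tags with position in `[center - flank, center + flank)` where
#' `center = floor((start + end) / 2)`. Strand is ignored.
#'
#' @param track a [tag_track()].
#' @param interval a one-row interval data frame (or a row index into a larger
#'   table via `interval[i, ]`).
#' @param flank half-window in bp.
#' @return integer tag count.
#' @export
count_in_window <- function(track, interval, flank) {
  .check_intervals(interval)
  ctr <- interval_center(interval)
  n <- vapply(seq_len(nrow(interval)), function(i) {
    .count_range(track$tags[[interval$chrom[i]]], ctr[i] - flank, ctr[i] + flank)
  }, numeric(1))
  as.integer(n)
}

#' Mean read density per kilobase around interval centers
#'
#' The quantity behind the positivity filter: tag count in the +/- `flank`
#' window divided by the window size in Kb. With the default `flank = 1000`
#' this is "reads on average within 1 Kb".
#'
#' @inheritParams count_in_window
#' @return numeric reads-per-Kb values.
#' @export
mean_reads_per_kb <- function(track, interval, flank = 1000) {
  stopifnot(flank > 0)
  count_in_window(track, interval, flank) / (2 * flank / 1000)
}

# Per-anchor binned offset counts: rows = anchors, cols = offset bins of width
# `bin` covering [-flank, flank). Shared by profiles and heat-maps so their
# aggregates agree by construction.
.bin_offsets <- function(track, anchors, flank, bin) {
  nb <- as.integer(2 * flank / bin)
  ctr <- interval_center(anchors)
  m <- matrix(0L, nrow = nrow(anchors), ncol = nb)
  for (i in seq_len(nrow(anchors))) {
    pos <- track$tags[[anchors$chrom[i]]]
    if (is.null(pos) || !length(pos)) next
    j <- findInterval(c(ctr[i] - flank - 1, ctr[i] + flank - 1), pos)
    if (j[2] > j[1]) {
      off <- pos[(j[1] + 1):j[2]] - ctr[i]
      m[i, ] <- tabulate((off + flank) %/% bin + 1, nbins = nb)
    }
  }
  rownames(m) <- if (!is.null(anchors$id)) anchors$id else as.character(seq_len(nrow(anchors)))
  m
}

# TRUE where the anchor's nearest TSS lies at a genomic position >= the anchor
# center (offset axis already points toward the TSS); FALSE means flip.
.tss_keep_orientation <- function(anchors, genes) {
  nt <- nearest_tss(anchors, genes)
  tsspos <- genes$tss[match(nt$gene_id, genes$gene_id)]
  tsspos >= interval_center(anchors)
}

#' IgG-normalized average signal profile around anchors
#'
#' For each offset bin the treatment and IgG tag counts are summed over all
#' anchors, depth-normalized by their library sizes, and the profile value is
#' the ratio `(T_b / N_T) / ((G_b + pseudocount) / N_G)` — fold enrichment over
#' the IgG background. When a gene table is supplied, each anchor's offset axis
#' is flipped so that its nearest TSS lies at positive offsets before
#' averaging (the "direction of the nearest TSS" orientation).
#'
#' @param treatment,igg [tag_track()] objects (both non-empty).
#' @param anchors interval data frame of anchor regions (profile is centered on
#'   their centers).
#' @param flank half-window in bp (default 3000).
#' @param bin bin width in bp (default 50); `2 * flank` must be a multiple.
#' @param genes optional gene model table for TSS orientation.
#' @param pseudocount added to the per-bin IgG count (tags/bin) before the
#'   ratio; guards empty background bins.
#' @return an object of class `binned_signal`: data frame with `offset` (bin
#'   centers), summed `treatment` and `igg` counts, and the normalized `value`.
#' @export
igg_normalized_profile <- function(treatment, igg, anchors, flank = 3000,
                                   bin = 50, genes = NULL, pseudocount = 0.5) {
  .check_intervals(anchors, "anchors")
  if (!nrow(anchors)) stop("empty anchor set")
  if (treatment$library_size == 0 || igg$library_size == 0)
    stop("treatment and IgG tracks must be non-empty")
  if ((2 * flank) %% bin != 0) stop("2*flank must be a multiple of bin")
  tm <- .bin_offsets(treatment, anchors, flank, bin)
  gm <- .bin_offsets(igg, anchors, flank, bin)
  if (!is.null(genes)) {
    keep <- .tss_keep_orientation(anchors, genes)
    flip <- which(!keep)
    if (length(flip)) {
      tm[flip, ] <- tm[flip, rev(seq_len(ncol(tm))), drop = FALSE]
      gm[flip, ] <- gm[flip, rev(seq_len(ncol(gm))), drop = FALSE]
    }
  }
  tb <- colSums(tm); gb <- colSums(gm)
  value <- (tb / treatment$library_size) / ((gb + pseudocount) / igg$library_size)
  nb <- length(tb)
  out <- data.frame(offset = -flank + bin / 2 + bin * (seq_len(nb) - 1),
                    treatment = tb, igg = gb, value = value)
  structure(out, class = c("binned_signal", "data.frame"),
            flank = flank, bin = bin, n_anchors = nrow(anchors),
            oriented = !is.null(genes))
}

#' Plot an average signal profile
#'
#' @param x a `binned_signal` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.binned_signal <- function(x, ...) {
  graphics::plot(x$offset, x$value, type = "l",
                 xlab = "offset from anchor center (bp)",
                 ylab = "signal / IgG", ...)
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}

#' Per-anchor signal heat-map matrix
#'
#' One row per anchor, one column per offset bin of width `bin` covering
#' `[-flank, flank)`. Rows are keyed and ordered by anchor id, so the matrix is
#' invariant to permutations of the input anchor list; use [sort_heatmap()] to
#' apply a fold-change row order.
#'
#' @inheritParams igg_normalized_profile
#' @param track a [tag_track()].
#' @param normalize `"none"` for raw counts, `"depth"` to scale counts by
#'   `depth_ref / library_size`.
#' @param depth_ref reference library size for depth scaling (typically the
#'   smallest library in the comparison).
#' @return an object of class `heatmap_matrix` with elements `values`
#'   (numeric matrix), `offsets` (bin centers), `flank`, `bin`, `sample_id`.
#' @export
heatmap_matrix <- function(track, anchors, flank = 1000, bin = 50,
                           normalize = c("none", "depth"), depth_ref = NULL) {
  .check_intervals(anchors, "anchors")
  if (!nrow(anchors)) stop("empty anchor set")
  if ((2 * flank) %% bin != 0) stop("2*flank must be a multiple of bin")
  normalize <- match.arg(normalize)
  m <- .bin_offsets(track, anchors, flank, bin)
  m <- m[order(rownames(m)), , drop = FALSE]
  mode(m) <- "double"
  if (normalize == "depth") {
    if (is.null(depth_ref)) stop("depth normalization needs depth_ref")
    m <- m * depth_ref / track$library_size
  }
  nb <- ncol(m)
  structure(list(values = m,
                 offsets = -flank + bin / 2 + bin * (seq_len(nb) - 1),
                 flank = flank, bin = bin, sample_id = track$sample_id),
            class = "heatmap_matrix")
}

#' @export
print.heatmap_matrix <- function(x, ...) {
  cat("<heatmap_matrix>", x$sample_id, ":", nrow(x$values), "anchors x",
      ncol(x$values), "bins (", -x$flank, "..", x$flank, "bp )\n")
  invisible(x)
}

#' Reorder heat-map rows by a fold-change key
#'
#' Rows are sorted by `key` in decreasing order; ties are broken by row id
#' (lexicographic), so the order is fully deterministic.
#'
#' @param hm a [heatmap_matrix()] (or `ratiometric_matrix`).
#' @param key named numeric vector; names must cover the row ids.
#' @return the object with rows reordered.
#' @export
sort_heatmap <- function(hm, key) {
  ids <- rownames(if (inherits(hm, "heatmap_matrix")) hm$values else hm$log2_ratio)
  if (!all(ids %in% names(key))) stop("key must cover every row id")
  k <- key[ids]
  ord <- order(-k, ids)
  if (inherits(hm, "heatmap_matrix")) {
    hm$values <- hm$values[ord, , drop = FALSE]
  } else {
    hm$log2_ratio <- hm$log2_ratio[ord, , drop = FALSE]
    hm$rgb <- hm$rgb[ord, , , drop = FALSE]
  }
  hm
}

#' Ratiometric red/green/blue encoding of two heat-maps
#'
#' Encodes the per-cell knockout/wild-type change as colors: gain (ratio > 1)
#' in red, loss in blue, unchanged in green. The log2 ratio
#' `r = log2((ko + pseudocount) / (wt + pseudocount))` maps to
#' `RGB = (clip(r, 0, s)/s, 1 - min(|r|, s)/s, clip(-r, 0, s)/s)` with
#' saturation `s`.
#'
#' @param wt,ko [heatmap_matrix()] objects on identical grids.
#' @param saturation absolute log2 ratio at which a channel saturates.
#' @param pseudocount added to both matrices before the ratio.
#' @return an object of class `ratiometric_matrix` with `log2_ratio` (matrix)
#'   and `rgb` (anchors x bins x 3 array in \[0, 1\]).
#' @export
ratiometric_encode <- function(wt, ko, saturation = 2.0, pseudocount = 0.5) {
  if (!identical(dim(wt$values), dim(ko$values)) ||
      !identical(wt$offsets, ko$offsets) ||
      !identical(rownames(wt$values), rownames(ko$values)))
    stop("wt and ko heat-maps must share an identical grid")
  s <- saturation
  r <- log2((ko$values + pseudocount) / (wt$values + pseudocount))
  rgb <- array(0, dim = c(dim(r), 3),
               dimnames = list(rownames(r), NULL, c("R", "G", "B")))
  rgb[, , 1] <- pmin(pmax(r, 0), s) / s
  rgb[, , 2] <- 1 - pmin(abs(r), s) / s
  rgb[, , 3] <- pmin(pmax(-r, 0), s) / s
  structure(list(log2_ratio = r, rgb = rgb, saturation = s,
                 pseudocount = pseudocount, offsets = wt$offsets,
                 flank = wt$flank, bin = wt$bin),
            class = "ratiometric_matrix")
}

#' Render a ratiometric heat-map to PNG
#'
#' @param x a `ratiometric_matrix`.
#' @param path output PNG path.
#' @param width,height device size in pixels.
#' @export
render_ratiometric_png <- function(x, path, width = 400, height = 600) {
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(2, 1, 1, 1))
  graphics::plot(NA, xlim = range(x$offsets), ylim = c(0, nrow(x$log2_ratio)),
                 xlab = "offset (bp)", ylab = "", yaxt = "n", xaxs = "i", yaxs = "i")
  img <- grDevices::rgb(x$rgb[, , 1], x$rgb[, , 2], x$rgb[, , 3])
  dim(img) <- dim(x$log2_ratio)
  graphics::rasterImage(grDevices::as.raster(img), min(x$offsets),
                        0, max(x$offsets), nrow(x$log2_ratio),
                        interpolate = FALSE)
  invisible(path)
}

#' Export a profile as a per-bin table or bedGraph-ready frame
#'
#' @param profile a `binned_signal`.
#' @param anchors the anchor intervals the profile was built from (only used
#'   for provenance columns).
#' @return data frame suitable for [write_tsv()].
#' @export
profile_table <- function(profile, anchors = NULL) {
  out <- as.data.frame(profile)
  attr(out, "n_anchors") <- attr(profile, "n_anchors")
  out
}
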