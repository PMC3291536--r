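# Peak calling is a transparent Poisson sliding-window test against the IgG
# control: every threshold is an argument and the whole procedure is
# deterministic, so synthetic recovery experiments are exactly reproducible.

#' Call peaks against a control track
#'
#' Slides a window of `window` bp in steps of `step` bp along every
#' chromosome. A window is enriched when its treatment tag count is at least
#' `min_fold` times the local expectation and its upper-tail Poisson p-value is
#' at most `p_max`; the expectation is
#' `lambda = max(control count scaled by N_T/N_C, genome-wide treatment rate x
#' window)`. Enriched windows closer than `merge_gap` bp are merged; the summit
#' is the center of the max-count `step`-bp bin within the merged interval
#' (leftmost on ties).
#'
#' @param treatment,control [tag_track()] objects; `control` is typically IgG
#'   and must be non-empty.
#' @param window window width in bp.
#' @param step slide step in bp.
#' @param min_fold minimum fold enrichment over `lambda`.
#' @param p_max Poisson p-value cutoff.
#' @param merge_gap merge enriched windows separated by at most this many bp.
#' @param chrom_lengths named vector of chromosome lengths; defaults to the
#'   track's own (or the max tag position + 1).
#' @return interval data frame with `id`, `summit`, `enrichment`, `p_value`.
#' @export
call_peaks <- function(treatment, control, window = 200, step = 50,
                       min_fold = 4, p_max = 1e-5, merge_gap = 200,
                       chrom_lengths = NULL) {
  if (is.null(chrom_lengths)) chrom_lengths <- treatment$chrom_lengths
  if (is.null(chrom_lengths))
    chrom_lengths <- vapply(treatment$tags, function(p) max(p, 0) + 1, numeric(1))
  if (control$library_size == 0) stop("control track has library size 0")
  if (treatment$library_size == 0) stop("treatment track has library size 0")
  genome_len <- sum(chrom_lengths)
  bg_rate <- treatment$library_size / genome_len
  depth <- treatment$library_size / control$library_size
  res <- list()
  for (ch in names(chrom_lengths)) {
    len <- chrom_lengths[[ch]]
    if (len < window) next
    starts <- seq(0, len - window, by = step)
    tp <- treatment$tags[[ch]]
    cp <- control$tags[[ch]]
    tc <- if (length(tp)) findInterval(starts + window - 1, tp) - findInterval(starts - 1, tp) else rep(0L, length(starts))
    cc <- if (length(cp)) findInterval(starts + window - 1, cp) - findInterval(starts - 1, cp) else rep(0L, length(starts))
    lambda <- pmax(cc * depth, bg_rate * window)
    pv <- stats::ppois(tc - 1, lambda, lower.tail = FALSE)
    keep <- which(tc >= min_fold * lambda & pv <= p_max & tc > 0)
    if (!length(keep)) next
    # merge enriched windows whose gap is <= merge_gap
    ws <- starts[keep]; we <- ws + window
    brk <- c(TRUE, ws[-1] - we[-length(we)] > merge_gap)
    grp <- cumsum(brk)
    for (g in unique(grp)) {
      idx <- keep[grp == g]
      ps <- starts[idx[1]]; pe <- starts[idx[length(idx)]] + window
      # summit: max-count step-bp bin, refined to the local center of mass of
      # the tags within +/- window/2 of that bin (sub-bin accuracy)
      bs <- seq(ps, pe - step, by = step)
      bc <- if (length(tp)) findInterval(bs + step - 1, tp) - findInterval(bs - 1, tp) else rep(0L, length(bs))
      smt <- bs[which.max(bc)] + step %/% 2
      j0 <- findInterval(c(smt - window / 2 - 1, smt + window / 2 - 1), tp)
      if (j0[2] > j0[1]) smt <- round(mean(tp[(j0[1] + 1):j0[2]]))
      cnt <- .count_range(tp, ps, pe)
      ctl <- .count_range(cp, ps, pe)
      lam <- max(ctl * depth, bg_rate * (pe - ps))
      res[[length(res) + 1]] <- data.frame(
        chrom = ch, start = ps, end = pe,
        id = sprintf("%s_%d", ch, as.integer(ps)),
        summit = smt, enrichment = cnt / lam,
        p_value = stats::ppois(cnt - 1, lam, lower.tail = FALSE),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res))
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      id = character(), summit = numeric(),
                      enrichment = numeric(), p_value = numeric()))
  out <- do.call(rbind, res)
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Overlap two interval sets
#'
#' Half-open interval intersection after expanding both sides by `slop` bp.
#' `[10, 20)` and `[20, 30)` do not overlap at `slop = 0`.
#'
#' @param a,b interval data frames (ids are taken from `id` or row numbers).
#' @param slop symmetric slop in bp.
#' @return list with `pairs` (data frame of `a_id`, `b_id`), `n_a_hit` (a
#'   intervals with at least one partner), `n_b_hit`.
#' @export
overlap_intervals <- function(a, b, slop = 0) {
  .check_intervals(a, "a"); .check_intervals(b, "b")
  aid <- if (!is.null(a$id)) a$id else as.character(seq_len(nrow(a)))
  bid <- if (!is.null(b$id)) b$id else as.character(seq_len(nrow(b)))
  pairs <- list()
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ai <- which(a$chrom == ch); bi <- which(b$chrom == ch)
    bs <- b$start[bi] - slop; be <- b$end[bi] + slop
    ord <- order(bs)
    bs <- bs[ord]; be <- be[ord]; bidx <- bi[ord]
    for (i in ai) {
      hit <- which(bs < a$end[i] + slop & be > a$start[i] - slop)
      if (length(hit))
        pairs[[length(pairs) + 1]] <- data.frame(
          a_id = aid[i], b_id = bid[bidx[hit]], stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(a_id = character(), b_id = character())
  list(pairs = pairs,
       n_a_hit = length(unique(pairs$a_id)),
       n_b_hit = length(unique(pairs$b_id)))
}

#' Signed strand-oriented distance to the nearest TSS
#'
#' For each interval center `x` the distance to a gene's TSS is `x - tss` on
#' `+` strand genes and `tss - x` on `-` strand genes, so negative values are
#' upstream of the gene. The nearest gene is chosen by absolute distance; ties
#' go to the smaller `gene_id`.
#'
#' @param peaks interval data frame.
#' @param genes gene model table.
#' @return data frame with `peak_id`, `gene_id`, `distance`.
#' @export
nearest_tss <- function(peaks, genes) {
  .check_intervals(peaks, "peaks")
  if (!nrow(genes)) stop("gene table is empty")
  pid <- if (!is.null(peaks$id)) peaks$id else as.character(seq_len(nrow(peaks)))
  ctr <- interval_center(peaks)
  out_gene <- character(nrow(peaks)); out_d <- numeric(nrow(peaks))
  for (ch in unique(peaks$chrom)) {
    gi <- which(genes$chrom == ch)
    pi <- which(peaks$chrom == ch)
    if (!length(gi)) {
      # fall back to genome-wide nearest is meaningless across chromosomes
      out_gene[pi] <- NA_character_; out_d[pi] <- Inf
      next
    }
    ord <- gi[order(genes$tss[gi], genes$gene_id[gi])]
    tsss <- genes$tss[ord]
    for (i in pi) {
      k <- findInterval(ctr[i], tsss)
      cand <- unique(pmin(pmax(c(k, k + 1), 1), length(tsss)))
      # widen to all genes sharing the candidate TSS coordinates (id tie-break)
      cand <- which(tsss %in% tsss[cand])
      dabs <- abs(ctr[i] - tsss[cand])
      best <- cand[dabs == min(dabs)]
      best <- best[order(genes$gene_id[ord[best]])][1]
      g <- ord[best]
      out_gene[i] <- genes$gene_id[g]
      out_d[i] <- if (genes$strand[g] == "+") ctr[i] - genes$tss[g]
                  else genes$tss[g] - ctr[i]
    }
  }
  data.frame(peak_id = pid, gene_id = out_gene, distance = out_d,
             stringsAsFactors = FALSE)
}

#' CpG-island proximity of peaks
#'
#' A peak overlapping an island records the center-to-center distance and is
#' proximal. Otherwise the border-to-border gap to the nearest island is
#' recorded and the peak is proximal iff the gap is at most `max_gap` bp
#' (boundary included). With no islands every peak is distal with distance
#' `Inf`.
#'
#' @param peaks interval data frame.
#' @param islands interval data frame of CpG islands (may be empty).
#' @param max_gap proximity cutoff in bp (default 1000).
#' @return data frame with `peak_id`, `distance` (center-to-center when
#'   overlapping, else the gap), `gap`, `overlaps`, `label`
#'   (`"proximal"`/`"distal"`).
#' @export
cpg_distance <- function(peaks, islands, max_gap = 1000) {
  .check_intervals(peaks, "peaks")
  pid <- if (!is.null(peaks$id)) peaks$id else as.character(seq_len(nrow(peaks)))
  n <- nrow(peaks)
  out <- data.frame(peak_id = pid, distance = rep(Inf, n), gap = rep(Inf, n),
                    overlaps = rep(FALSE, n),
                    label = rep("distal", n), stringsAsFactors = FALSE)
  if (is.null(islands) || !nrow(islands)) return(out)
  .check_intervals(islands, "islands")
  pc <- interval_center(peaks)
  for (ch in unique(peaks$chrom)) {
    ii <- which(islands$chrom == ch)
    pi <- which(peaks$chrom == ch)
    if (!length(ii)) next
    is_s <- islands$start[ii]; is_e <- islands$end[ii]
    ic <- floor((is_s + is_e) / 2)
    for (i in pi) {
      gaps <- pmax(is_s - peaks$end[i], peaks$start[i] - is_e)
      j <- which.min(gaps)
      if (gaps[j] < 0) {                    # interval intersection
        out$overlaps[i] <- TRUE
        out$gap[i] <- 0
        out$distance[i] <- pc[i] - ic[j]    # center-to-center, signed
        out$label[i] <- "proximal"
      } else {
        out$gap[i] <- gaps[j]
        out$distance[i] <- gaps[j]
        out$label[i] <- if (gaps[j] <= max_gap) "proximal" else "distal"
      }
    }
  }
  out
}

# Symmetric signed log-scale distance bin. |d| below `linear` falls in bin 0;
# beyond that, bins advance every 1/n_per_decade decades, carrying the sign.
.tss_distance_bin <- function(d, linear = 1000, n_per_decade = 3) {
  b <- integer(length(d))
  big <- which(abs(d) >= linear & is.finite(d))
  if (length(big)) {
    k <- 1 + floor(n_per_decade * log10(abs(d[big]) / linear))
    b[big] <- as.integer(sign(d[big]) * k)
  }
  b[!is.finite(d)] <- NA_integer_
  b
}

# Nearest-TSS signed distance of arbitrary genomic positions (vector form used
# by the matched-control sampler).
.signed_tss_distance <- function(chrom, pos, genes) {
  n <- length(pos)
  out <- rep(Inf, n)
  for (ch in unique(chrom)) {
    gi <- which(genes$chrom == ch)
    pi <- which(chrom == ch)
    if (!length(gi)) next
    ord <- gi[order(genes$tss[gi], genes$gene_id[gi])]
    tsss <- genes$tss[ord]
    for (i in pi) {
      k <- findInterval(pos[i], tsss)
      cand <- unique(pmin(pmax(c(k, k + 1), 1), length(tsss)))
      cand <- which(tsss %in% tsss[cand])
      dabs <- abs(pos[i] - tsss[cand])
      best <- cand[dabs == min(dabs)]
      best <- best[order(genes$gene_id[ord[best]])][1]
      g <- ord[best]
      out[i] <- if (genes$strand[g] == "+") pos[i] - genes$tss[g]
                else genes$tss[g] - pos[i]
    }
  }
  out
}

#' TSS-distance-matched random control regions
#'
#' Draws one random control region per peak such that the controls' signed
#' nearest-TSS distance distribution matches the peaks' exactly at bin
#' resolution. Distances are binned on a symmetric log scale (a single linear
#' bin for |d| < 1 Kb, then `n_bins_per_decade` bins per decade on each side).
#' Each control keeps its source peak's width, is drawn uniformly among
#' genomic positions whose nearest-TSS distance falls in the same bin, and is
#' rejected if it intersects any source peak or a previously accepted control.
#'
#' @param peaks interval data frame.
#' @param genes gene model table.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param seed integer seed; two seeds give different controls but identical
#'   bin histograms.
#' @param n_bins_per_decade log-bin resolution.
#' @param max_tries rejection-sampling budget per peak.
#' @return object of class `matched_controls`: list with `controls` (interval
#'   data frame), `peak_bins`, `control_bins`, `bin_counts`, `seed`.
#' @export
matched_controls <- function(peaks, genes, chrom_lengths, seed = 1,
                             n_bins_per_decade = 3, max_tries = 10000) {
  .check_intervals(peaks, "peaks")
  if (!nrow(peaks)) stop("empty peak set")
  pid <- if (!is.null(peaks$id)) peaks$id else as.character(seq_len(nrow(peaks)))
  d_peak <- .signed_tss_distance(peaks$chrom, interval_center(peaks), genes)
  peak_bins <- .tss_distance_bin(d_peak, n_per_decade = n_bins_per_decade)
  chroms <- names(chrom_lengths)
  probs <- chrom_lengths / sum(chrom_lengths)
  taken <- lapply(chroms, function(ch) peaks[peaks$chrom == ch, c("start", "end")])
  names(taken) <- chroms
  set.seed(seed)
  ctrl <- vector("list", nrow(peaks))
  ctrl_bins <- integer(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    w <- peaks$end[i] - peaks$start[i]
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      ch <- sample(chroms, 1, prob = probs)
      len <- chrom_lengths[[ch]]
      ctr <- floor(stats::runif(1, w / 2, len - w / 2))
      d <- .signed_tss_distance(ch, ctr, genes)
      if (is.na(peak_bins[i])) break
      if (!identical(.tss_distance_bin(d, n_per_decade = n_bins_per_decade),
                     peak_bins[i])) next
      cs <- ctr - floor(w / 2); ce <- cs + w
      occ <- taken[[ch]]
      if (nrow(occ) && any(occ$start < ce & occ$end > cs)) next
      taken[[ch]] <- rbind(occ, data.frame(start = cs, end = ce))
      ctrl[[i]] <- data.frame(chrom = ch, start = cs, end = ce,
                              id = paste0("ctrl_", pid[i]),
                              stringsAsFactors = FALSE)
      ctrl_bins[i] <- peak_bins[i]
      ok <- TRUE
      break
    }
    if (!ok)
      stop("could not place a matched control for peak ", pid[i],
           " (TSS-distance bin ", peak_bins[i], ") after ", max_tries, " tries")
  }
  controls <- do.call(rbind, ctrl)
  bins <- sort(unique(peak_bins))
  bin_counts <- data.frame(
    bin = bins,
    peaks = as.integer(table(factor(peak_bins, levels = bins))),
    controls = as.integer(table(factor(ctrl_bins, levels = bins))))
  structure(list(controls = controls, peak_bins = peak_bins,
                 control_bins = ctrl_bins, bin_counts = bin_counts,
                 seed = seed, n_bins_per_decade = n_bins_per_decade),
            class = "matched_controls")
}

#' @export
print.matched_controls <- function(x, ...) {
  cat("<matched_controls>", nrow(x$controls), "controls in",
      nrow(x$bin_counts), "TSS-distance bins (seed", x$seed, ")\n")
  invisible(x)
}
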