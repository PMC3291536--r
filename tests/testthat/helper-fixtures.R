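# Shared fixtures and independent brute-force oracles. The full-scale study
# simulation is cached: several files (and the acceptance checks) reuse it.

.fixtures <- new.env(parent = emptyenv())

# Default-scale synthetic study (2 x 10 Mb, 1000 genes, 600 planted sites),
# seed fixed at 1.
default_sim <- function() {
  if (is.null(.fixtures$sim)) {
    cfg <- sim_config(seed = 1)
    genome <- make_genome(cfg)
    sites <- plant_sites(genome, cfg)
    tracks <- simulate_tags(genome, sites, cfg)
    peaks <- call_peaks(tracks$rest_wt, tracks$igg_wt,
                        chrom_lengths = genome$chrom_lengths)
    .fixtures$sim <- list(cfg = cfg, genome = genome, sites = sites,
                          tracks = tracks, peaks = peaks)
  }
  .fixtures$sim
}

# A small, fast study for tests that only need plumbing, not statistics.
small_cfg <- function(seed = 1, ...) {
  defaults <- list(chrom_lengths = c(chrA = 2e6, chrB = 2e6),
                   n_genes = 200,
                   n_sites = c(rest_dependent_loss = 20, cpg_gain = 20,
                               unchanged = 20, background_control = 0))
  do.call(sim_config,
          c(list(seed = seed), utils::modifyList(defaults, list(...))))
}

# Tag track built from explicit positions.
track_from_positions <- function(..., sample_id = "t", chrom_lengths = NULL) {
  tag_track(list(...), sample_id = sample_id, chrom_lengths = chrom_lengths)
}

# --- independent oracles -----------------------------------------------------

# exhaustive window count
naive_count <- function(track, chrom, center, flank) {
  pos <- track$tags[[chrom]]
  if (is.null(pos)) return(0L)
  sum(pos >= center - flank & pos < center + flank)
}

# all-pairs interval overlap with slop
naive_overlap_pairs <- function(a, b, slop = 0) {
  out <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] == b$chrom[j] &&
        a$start[i] - slop < b$end[j] + slop &&
        a$end[i] + slop > b$start[j] - slop)
      out[[length(out) + 1]] <- c(a$id[i], b$id[j])
  }
  if (!length(out)) return(data.frame(a_id = character(), b_id = character()))
  m <- do.call(rbind, out)
  data.frame(a_id = m[, 1], b_id = m[, 2], stringsAsFactors = FALSE)
}

# linear-scan nearest TSS with the same sign and tie conventions
naive_nearest_tss <- function(center, chrom, genes) {
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  d <- abs(center - g$tss)
  hit <- g[d == min(d), , drop = FALSE]
  hit <- hit[order(hit$gene_id), , drop = FALSE][1, ]
  dist <- if (hit$strand == "+") center - hit$tss else hit$tss - center
  list(gene_id = hit$gene_id, distance = dist)
}

# per-gene linear scan of the co-occurrence indicator
naive_indicator <- function(peaks, gene, offsets, window) {
  ctr <- interval_center(peaks[peaks$chrom == gene$chrom, , drop = FALSE])
  a <- if (gene$strand == "+") gene$tss else gene$tss
  vapply(offsets, function(k) {
    off <- if (gene$strand == "+") ctr - gene$tss else gene$tss - ctr
    any(off >= k - window / 2 & off < k + window / 2)
  }, logical(1))
}
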