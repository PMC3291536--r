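test_that("no peaks are called on pure background", {
  # 2 Mb at 2.5e-4 tags/bp: the minimal significant window count is 4
  # (Poisson tail 2.5e-7), so the expected number of false windows is ~0.01
  set.seed(1)
  len <- 2e6; rate <- 2.5e-4
  tr <- track_from_positions(chr1 = floor(stats::runif(rpois(1, rate * len),
                                                       0, len)),
                             chrom_lengths = c(chr1 = len))
  ig <- track_from_positions(chr1 = floor(stats::runif(rpois(1, rate * len),
                                                       0, len)),
                             chrom_lengths = c(chr1 = len))
  pk <- call_peaks(tr, ig, chrom_lengths = c(chr1 = len))
  expect_equal(nrow(pk), 0)
  expect_error(call_peaks(tr, track_from_positions(chr1 = numeric(0))),
               "library size 0")
})

test_that("planted sites are recovered with accurate summits", {
  set.seed(2)
  len <- 5e6; rate <- 0.001
  centers <- seq(2e4, by = 45000, length.out = 100)
  focal <- unlist(lapply(centers, function(c0)
    round(stats::rnorm(rpois(1, 50), c0, 100))))
  tr <- track_from_positions(
    chr1 = c(floor(stats::runif(rpois(1, rate * len), 0, len)), focal),
    chrom_lengths = c(chr1 = len))
  ig <- track_from_positions(chr1 = floor(stats::runif(rpois(1, rate * len),
                                                       0, len)),
                             chrom_lengths = c(chr1 = len))
  pk <- call_peaks(tr, ig, chrom_lengths = c(chr1 = len))
  hit <- vapply(centers, function(c0) {
    j <- which(pk$start <= c0 & pk$end > c0)
    length(j) == 1 && abs(pk$summit[j] - c0) <= 100
  }, logical(1))
  expect_gte(sum(hit), 95)
})

test_that("strong peak calls are invariant to doubling both libraries", {
  # significance grows with depth, so borderline background windows can cross
  # the threshold; the planted (strongly enriched) calls must not move
  sim <- default_sim()
  dup <- function(t) tag_track(lapply(t$tags, function(p) rep(p, 2)),
                               sample_id = t$sample_id,
                               chrom_lengths = t$chrom_lengths)
  pk1 <- call_peaks(sim$tracks$rest_wt, sim$tracks$igg_wt,
                    chrom_lengths = sim$genome$chrom_lengths)
  pk2 <- call_peaks(dup(sim$tracks$rest_wt), dup(sim$tracks$igg_wt),
                    chrom_lengths = sim$genome$chrom_lengths)
  # boundaries may widen by a step (flanking windows gain significance), but
  # each planted Rest site keeps exactly one call with an identical summit
  rest_sites <- sim$sites$sites[
    sim$sites$sites$site_class != "background_control", ]
  summit_at <- function(pk) {
    prs <- overlap_intervals(rest_sites, pk)$pairs
    stats::setNames(pk$summit[match(prs$b_id, pk$id)], prs$a_id)
  }
  s1 <- summit_at(pk1); s2 <- summit_at(pk2)
  expect_equal(length(s1), nrow(rest_sites))
  expect_identical(s1[order(names(s1))], s2[order(names(s2))])
})

test_that("interval overlap is half-open and matches the all-pairs oracle", {
  a <- intervals("chr1", 10, 20, id = "a1")
  expect_equal(overlap_intervals(a, intervals("chr1", 20, 30, id = "b1"))$n_a_hit, 0)
  expect_equal(overlap_intervals(a, intervals("chr1", 19, 30, id = "b1"))$n_a_hit, 1)
  set.seed(3)
  mk <- function(n, prefix) {
    s <- sample.int(5e4, n)
    intervals(sample(c("chr1", "chr2"), n, replace = TRUE), s,
              s + sample.int(2000, n), id = paste0(prefix, seq_len(n)))
  }
  a <- mk(150, "a"); b <- mk(120, "b")
  got <- overlap_intervals(a, b)$pairs
  want <- naive_overlap_pairs(a, b)
  key <- function(d) sort(paste(d$a_id, d$b_id))
  expect_identical(key(got), key(want))
})

test_that("nearest TSS distances are signed, oriented and oracle-exact", {
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                      strand = c("+", "-"), tss = c(1500, 700),
                      te = c(3000, 100), stringsAsFactors = FALSE)
  pk <- intervals("chr1", 1090, 1110, id = "p")    # center 1100
  # plus strand, TSS at 1500: upstream of the gene -> -400
  nt_plus <- nearest_tss(pk, genes[genes$gene_id == "gA", ])
  expect_equal(nt_plus$distance, -400)             # center - tss
  # minus strand, TSS at 700: also upstream -> -400 (strand symmetry)
  nt_minus <- nearest_tss(pk, genes[genes$gene_id == "gB", ])
  expect_equal(nt_minus$distance, -400)            # tss - center
  # both genes are 400 bp away: the tie goes to the smaller gene_id
  expect_equal(nearest_tss(pk, genes)$gene_id, "gA")

  set.seed(4)
  sim_genes <- data.frame(gene_id = sprintf("g%03d", 1:80), chrom = "chr1",
                          strand = sample(c("+", "-"), 80, replace = TRUE),
                          tss = sample.int(1e6, 80), stringsAsFactors = FALSE)
  sim_genes$te <- sim_genes$tss + ifelse(sim_genes$strand == "+", 5000, -5000)
  s <- sample.int(1e6 - 200, 60)
  pks <- intervals("chr1", s, s + 200, id = sprintf("p%02d", 1:60))
  nt <- nearest_tss(pks, sim_genes)
  for (i in 1:60) {
    want <- naive_nearest_tss(interval_center(pks)[i], "chr1", sim_genes)
    expect_equal(nt$gene_id[i], want$gene_id)
    expect_equal(nt$distance[i], want$distance)
  }
})

test_that("CpG proximity follows the border-gap rule with 1 Kb boundary", {
  islands <- intervals("chr1", 5900, 6500, id = "i1")
  pk <- intervals("chr1", 5000, 5200, id = "p1")
  cg <- cpg_distance(pk, islands)
  expect_equal(cg$gap, 700)
  expect_equal(cg$label, "proximal")

  pk2 <- intervals("chr1", 3900, 4900, id = "p2")   # gap exactly 1000
  expect_equal(cpg_distance(pk2, islands)$label, "proximal")
  pk3 <- intervals("chr1", 3000, 4800, id = "p3")   # gap 1100
  expect_equal(cpg_distance(pk3, islands)$label, "distal")

  inside <- intervals("chr1", 6000, 6100, id = "p4")  # contained in island
  cg4 <- cpg_distance(inside, islands)
  expect_true(cg4$overlaps)
  expect_equal(cg4$gap, 0)
  expect_equal(cg4$distance, 6050 - 6200)             # center-to-center
  # no islands at all: distal with infinite distance
  none <- cpg_distance(pk, islands[0, ])
  expect_equal(none$label, "distal")
  expect_equal(none$distance, Inf)
})

test_that("matched controls match the TSS histogram exactly and avoid peaks", {
  sim <- default_sim()
  mc <- matched_controls(sim$peaks, sim$genome$genes,
                         sim$genome$chrom_lengths, seed = 11)
  expect_identical(mc$bin_counts$peaks, mc$bin_counts$controls)
  expect_equal(overlap_intervals(mc$controls, sim$peaks)$n_a_hit, 0)
  expect_equal(nrow(mc$controls), nrow(sim$peaks))
  # controls do not overlap one another
  self <- overlap_intervals(mc$controls, mc$controls)$pairs
  expect_true(all(self$a_id == self$b_id))
  # a different seed moves the controls but keeps the histogram
  mc2 <- matched_controls(sim$peaks[1:100, ], sim$genome$genes,
                          sim$genome$chrom_lengths, seed = 12)
  mc3 <- matched_controls(sim$peaks[1:100, ], sim$genome$genes,
                          sim$genome$chrom_lengths, seed = 13)
  expect_false(identical(mc2$controls$start, mc3$controls$start))
  expect_identical(mc2$bin_counts, mc3$bin_counts)
})

test_that("matched controls score PcG-positive near the background rate", {
  sim <- default_sim()
  qt <- sim$tracks[c("rnf2_wt", "rnf2_ko")]
  tab <- peak_signal_table(sim$peaks, qt)
  mc <- matched_controls(sim$peaks, sim$genome$genes,
                         sim$genome$chrom_lengths, seed = 21)
  ctab <- peak_signal_table(mc$controls, qt)
  ratio <- mean(tab$rnf2_positive) / mean(ctab$rnf2_positive)
  expect_gt(ratio, 3)    # planted sites score positive several-fold more often
  expect_lt(ratio, 8)
})
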