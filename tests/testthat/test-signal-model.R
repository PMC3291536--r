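test_that("windowed counts match a brute-force scan and simple plants", {
  set.seed(1)
  track <- track_from_positions(chr1 = sample.int(1e5, 5000, replace = TRUE),
                                chr2 = sample.int(1e5, 3000, replace = TRUE))
  for (i in 1:100) {
    ch <- sample(c("chr1", "chr2"), 1)
    ctr <- sample.int(1e5, 1)
    flank <- sample(c(100, 500, 1000, 3000), 1)
    iv <- intervals(ch, max(0, ctr - 10), ctr + 10)
    expect_identical(count_in_window(track, iv, flank),
                     as.integer(naive_count(track, ch, interval_center(iv), flank)))
  }
  # explicit plants
  t2 <- track_from_positions(chr1 = c(995, 1000, 1001, 1400, 1999, 1999, 150,
                                      2000, 5000))
  iv <- intervals("chr1", 900, 1100)        # center 1000
  expect_equal(count_in_window(t2, iv, 1000), 7)   # [0, 2000): 2000 excluded
  expect_equal(count_in_window(track_from_positions(chr1 = numeric(0)), iv, 1000), 0)
})

test_that("mean reads per Kb scales with the window", {
  t <- track_from_positions(chr1 = seq(550, 1450, 100))  # 10 tags in [500,1500)
  iv <- intervals("chr1", 990, 1010)                     # center 1000
  expect_equal(mean_reads_per_kb(t, iv, 1000), 5.0)
  expect_equal(mean_reads_per_kb(t, iv, 500), 10.0)      # same tags, half window
  expect_equal(mean_reads_per_kb(track_from_positions(chr1 = numeric(0)), iv), 0)
})

test_that("IgG-normalized profiles locate planted signal and are flat on null", {
  # single anchor, all treatment at the center, uniform IgG
  set.seed(2)
  tr <- track_from_positions(chr1 = rep(50000, 200))
  ig <- track_from_positions(chr1 = sample.int(1e5, 5000, replace = TRUE))
  anchors <- intervals("chr1", 49900, 50100, id = "a1")
  pr <- igg_normalized_profile(tr, ig, anchors)
  expect_lt(abs(pr$offset[which.max(pr$value)]), 50)   # argmax in the 0 bin

  # treatment drawn from the same law as IgG: profile ~ 1
  sim <- default_sim()
  null_pr <- igg_normalized_profile(sim$tracks$igg_ko, sim$tracks$igg_wt,
                                    sim$peaks)
  expect_gt(mean(null_pr$value), 0.8)
  expect_lt(mean(null_pr$value), 1.2)
  expect_error(igg_normalized_profile(tr, ig, anchors[0, ]), "empty anchor")
})

test_that("a planted Gaussian peak is recovered in center and spread", {
  set.seed(3)
  n_anchor <- 100; intensity <- 100; sdev <- 150
  centers <- seq(5e4, by = 1e4, length.out = n_anchor)
  pos <- unlist(lapply(centers, function(c0)
    round(stats::rnorm(intensity, c0, sdev))))
  tr <- track_from_positions(chr1 = pos)
  ig <- track_from_positions(chr1 = sample.int(2e6, 5e4, replace = TRUE))
  anchors <- intervals("chr1", centers - 100, centers + 100,
                       id = sprintf("a%03d", seq_along(centers)))
  pr <- igg_normalized_profile(tr, ig, anchors)
  # the argmax bin is within one 50-bp bin of the bin holding the true center
  expect_lte(abs(pr$offset[which.max(pr$value)]), 75)
  # weighted sd of the summed treatment counts recovers the spread within 20%
  w <- pr$treatment / sum(pr$treatment)
  mu <- sum(w * pr$offset)
  est_sd <- sqrt(sum(w * (pr$offset - mu)^2))
  expect_lt(abs(est_sd - sdev) / sdev, 0.2)
})

test_that("TSS orientation flips the profile exactly when strands flip", {
  # anchors inside gene bodies, asymmetric signal
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                      strand = c("+", "+"), tss = c(9000, 29000),
                      te = c(12000, 32000), stringsAsFactors = FALSE)
  tr <- track_from_positions(chr1 = c(rep(10500, 30), rep(30500, 10),
                                      rep(9800, 5)))
  ig <- track_from_positions(chr1 = seq(5000, 35000, by = 10))
  anchors <- intervals("chr1", c(9900, 29900), c(10100, 30100),
                       id = c("a1", "a2"))
  p1 <- igg_normalized_profile(tr, ig, anchors, flank = 2000, bin = 100,
                               genes = genes)
  flipped <- genes
  flipped$strand <- "-"
  flipped$tss <- genes$te
  flipped$te <- genes$tss
  p2 <- igg_normalized_profile(tr, ig, anchors, flank = 2000, bin = 100,
                               genes = flipped)
  expect_equal(p2$treatment, rev(p1$treatment))
  expect_equal(p2$igg, rev(p1$igg))
})

test_that("library-size scaling cancels in the normalized profile", {
  set.seed(4)
  tr <- track_from_positions(chr1 = sample.int(1e5, 2000, replace = TRUE))
  ig <- track_from_positions(chr1 = sample.int(1e5, 3000, replace = TRUE))
  anchors <- intervals("chr1", c(20000, 50000), c(20200, 50200),
                       id = c("a", "b"))
  dup <- function(t) track_from_positions(chr1 = rep(t$tags$chr1, 2))
  p1 <- igg_normalized_profile(tr, ig, anchors, pseudocount = 0)
  p2 <- igg_normalized_profile(dup(tr), dup(ig), anchors, pseudocount = 0)
  expect_equal(p1$value, p2$value)
})

test_that("heat-map rows are anchored, conserved and order-stable", {
  tr <- track_from_positions(chr1 = round(stats::rnorm(500, 50000, 200)))
  anchors <- intervals("chr1", c(9900, 49900, 89900), c(10100, 50100, 90100),
                       id = c("a1", "a2", "a3"))
  hm <- heatmap_matrix(tr, anchors)
  expect_equal(rownames(hm$values), c("a1", "a2", "a3"))
  expect_true(all(hm$values[c("a1", "a3"), ] == 0))
  expect_gt(sum(hm$values["a2", ]), 0)
  # column sums equal the profile numerator on the same grid
  ig <- track_from_positions(chr1 = seq(0, 1e5, by = 50))
  pr <- igg_normalized_profile(tr, ig, anchors, flank = 1000, bin = 50)
  expect_equal(unname(colSums(hm$values)), pr$treatment)
  # row order invariant under anchor permutation
  hm_perm <- heatmap_matrix(tr, anchors[c(3, 1, 2), ])
  expect_identical(hm$values, hm_perm$values)
})

test_that("ratiometric encoding honors identity, saturation and antisymmetry", {
  set.seed(5)
  tr <- track_from_positions(chr1 = sample.int(1e5, 4000, replace = TRUE))
  anchors <- intervals("chr1", c(30000, 60000), c(30200, 60200),
                       id = c("a", "b"))
  wt <- heatmap_matrix(tr, anchors)
  # identical matrices -> pure green
  enc <- ratiometric_encode(wt, wt)
  expect_true(all(enc$rgb[, , 1] == 0))
  expect_true(all(enc$rgb[, , 2] == 1))
  expect_true(all(enc$rgb[, , 3] == 0))
  # ko = 4 wt at saturation 2 -> pure red (pseudocount 0 keeps the ratio exact)
  ko <- wt; ko$values <- 4 * wt$values
  enc4 <- ratiometric_encode(wt, ko, saturation = 2, pseudocount = 0)
  pos_cells <- wt$values > 0
  expect_true(all(enc4$rgb[, , 1][pos_cells] == 1))
  expect_true(all(enc4$rgb[, , 2][pos_cells] == 0))
  expect_true(all(enc4$rgb[, , 3][pos_cells] == 0))
  # swapping the inputs swaps the red and blue channels
  ko2 <- wt; ko2$values <- wt$values + 3
  e12 <- ratiometric_encode(wt, ko2)
  e21 <- ratiometric_encode(ko2, wt)
  expect_equal(e12$rgb[, , 1], e21$rgb[, , 3])
  expect_equal(e12$rgb[, , 2], e21$rgb[, , 2])
  # mismatched grids are rejected
  other <- heatmap_matrix(tr, anchors, flank = 2000)
  expect_error(ratiometric_encode(wt, other), "identical grid")
})

test_that("heat-map rows sort by fold-change key with id tie-breaks", {
  tr <- track_from_positions(chr1 = c(rep(10000, 5), rep(20000, 5)))
  anchors <- intervals("chr1", c(9900, 19900, 29900), c(10100, 20100, 30100),
                       id = c("b", "a", "c"))
  hm <- heatmap_matrix(tr, anchors)
  key <- c(a = 2, b = 1, c = 2)
  srt <- sort_heatmap(hm, key)
  expect_equal(rownames(srt$values), c("a", "c", "b"))  # desc, id on ties
})
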