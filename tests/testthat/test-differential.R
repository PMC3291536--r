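# construct a minimal signal table by hand (attributes as set by the builder)
manual_table <- function(df) {
  class(df) <- c("peak_signal_table", "data.frame")
  attr(df, "genotypes") <- c("wt", "ko")
  df
}

test_that("ratio classification honors pseudocount, folds and boundaries", {
  expect_equal(classify_ratio(9, 4)$ratio, 0.5)
  expect_equal(classify_ratio(9, 4)$class, "decreased")
  expect_equal(classify_ratio(17, 17)$class, "unchanged")
  expect_equal(classify_ratio(0, 0)$ratio, 1)       # pseudocount guards 0/0
  expect_equal(classify_ratio(0, 0)$class, "unchanged")
  # exactly 1.5-fold counts as changed in both directions
  expect_equal(classify_ratio(1, 2)$class, "increased")   # (2+1)/(1+1) = 1.5
  expect_equal(classify_ratio(2, 1)$class, "decreased")   # (1+1)/(2+1) = 1/1.5
  # the three classes partition any input
  set.seed(1)
  cl <- classify_ratio(rpois(500, 10), rpois(500, 10))$class
  expect_true(all(cl %in% c("decreased", "unchanged", "increased")))
})

test_that("positivity filter keeps either-genotype signal above threshold", {
  tab <- manual_table(data.frame(
    peak_id = c("p1", "p2", "p3"),
    rnf2_wt_rpkb = c(6, 4.9, 0), rnf2_ko_rpkb = c(0, 4.9, 12)))
  expect_equal(positivity_filter(tab, "rnf2")$peak_id, c("p1", "p3"))
  expect_equal(nrow(positivity_filter(tab, "rnf2", threshold = 0)), 3)
  expect_equal(nrow(positivity_filter(tab, "rnf2", threshold = Inf)), 0)
  expect_error(positivity_filter(tab, "suz12"), "unknown factor")
})

test_that("chi-squared enrichment matches the closed form and a permutation null", {
  # 30/70 changed at peaks vs 10/90 at controls:
  # X2 = 200*(30*90 - 70*10)^2 / (100*100*40*160) = 12.5, p = 4.07e-4
  et <- chi2_enrichment(rep(c("decreased", "unchanged"), c(30, 70)),
                        rep(c("decreased", "unchanged"), c(10, 90)))
  expect_equal(et$statistic, 12.5, tolerance = 1e-12)
  expect_equal(et$p_value, stats::pchisq(12.5, 1, lower.tail = FALSE))
  # identical proportions: statistic 0, p 1
  same <- rep(c("decreased", "unchanged"), c(25, 75))
  et0 <- chi2_enrichment(same, same)
  expect_equal(et0$statistic, 0)
  expect_equal(et0$p_value, 1)
  # degenerate margin flagged
  etd <- chi2_enrichment(rep("unchanged", 10), rep("unchanged", 10))
  expect_true(etd$degenerate)
  expect_true(is.na(etd$p_value))
  # permutation oracle: shuffle membership labels, compare tail probabilities
  set.seed(2)
  x <- rep(c(1, 0, 1, 0), c(30, 70, 10, 90))
  grp <- rep(c("peak", "ctrl"), each = 100)
  stat <- function(g) {
    t <- table(g, x)
    suppressWarnings(unname(stats::chisq.test(t, correct = FALSE)$statistic))
  }
  perm <- replicate(2000, stat(sample(grp)))
  p_perm <- mean(perm >= 12.5 - 1e-9)
  expect_lt(abs(p_perm - et$p_value), 0.01)
})

test_that("level grouping separates planted low/high occupancy classes", {
  # 20 "loss" peaks: suz12 low, rnf2 4:1 down; 20 "gain": suz12 high, rnf2 1:4 up
  centers <- seq(5000, by = 5000, length.out = 40)
  cls <- rep(c("loss", "gain"), each = 20)
  pos_rnf2_wt <- rep(centers, each = 40)
  pos_rnf2_ko <- unlist(Map(function(c0, k) rep(c0, k), centers,
                            ifelse(cls == "loss", 10, 160)))
  pos_suz12 <- unlist(Map(function(c0, k) rep(c0, k), centers,
                          ifelse(cls == "loss", 2, 30)))
  tracks <- list(
    rnf2_wt = track_from_positions(chr1 = pos_rnf2_wt, sample_id = "rnf2_wt"),
    rnf2_ko = track_from_positions(chr1 = pos_rnf2_ko, sample_id = "rnf2_ko"),
    suz12_wt = track_from_positions(chr1 = pos_suz12, sample_id = "suz12_wt"),
    suz12_ko = track_from_positions(chr1 = pos_suz12, sample_id = "suz12_ko"))
  pks <- intervals("chr1", centers - 100, centers + 100,
                   id = sprintf("p%02d", 1:40))
  tab <- peak_signal_table(pks, tracks)
  gl <- group_by_level(tab, "suz12", "rnf2")
  expect_setequal(gl$scatter$group[cls == "loss"], "low")
  expect_setequal(gl$scatter$group[cls == "gain"], "high")
  expect_lt(gl$group_means[["low"]], log2(1 / 1.5))
  expect_gte(gl$group_means[["high"]], 0)
  # cutoff at infinity leaves a single low group
  gl_inf <- group_by_level(tab, "suz12", "rnf2", threshold = Inf)
  expect_setequal(gl_inf$scatter$group, "low")
})

test_that("density grids conserve counts and detect planted ratio shifts", {
  set.seed(3)
  n <- 200
  tab <- manual_table(data.frame(
    peak_id = sprintf("p%03d", 1:n),
    suz12_wt_rpkb = rep(c(2, 50), each = n / 2),
    suz12_ko_rpkb = rep(c(2, 50), each = n / 2),
    tss_distance = sample(c(-8000, -300, 2000, 40000), n, replace = TRUE),
    rnf2_ratio = 2^stats::rnorm(n, rep(c(0, 1), each = n / 2), 0.5)))
  dg <- density_grid(tab,
                     x_spec = list(type = "signal", factor = "suz12",
                                   genotype = "wt"),
                     y_spec = list(type = "distance", column = "tss_distance"),
                     ratio_factor = "rnf2")
  expect_equal(sum(dg$cells$count), n)
  expect_equal(sum(dg$x_marginal$count), n)
  expect_equal(sum(dg$y_marginal$count), n)
  # Welch between the lowest and highest occupied signal bins: planted
  # difference of 1 in log2 ratio at n=100/group, sd 0.5 -> overwhelming
  expect_lt(dg$welch$p.value, 1e-10)
  # identical ratios give a flat grid
  tab2 <- tab; tab2$rnf2_ratio <- 2
  dg2 <- density_grid(tab2, list(type = "signal", factor = "suz12"),
                      list(type = "distance", column = "tss_distance"), "rnf2")
  expect_true(all(dg2$cells$mean_log2_ratio == 1))
  # infinite distances go to the overflow bin, nothing is dropped
  tab3 <- tab; tab3$tss_distance[1:5] <- Inf
  dg3 <- density_grid(tab3, list(type = "signal", factor = "suz12"),
                      list(type = "distance", column = "tss_distance"), "rnf2")
  expect_equal(sum(dg3$cells$count), n)
  expect_true(1000L %in% dg3$y_marginal$y_bin)
})

test_that("log-log correlation of change vs parameter behaves", {
  n <- 395
  set.seed(4)
  ratio <- 2^stats::rnorm(n, 0, 0.6)
  tab <- manual_table(data.frame(peak_id = sprintf("p%03d", 1:n),
                                 rnf2_ratio = ratio,
                                 par_exact = ratio * 7,
                                 par_scaled = ratio * 7000,
                                 par_indep = exp(stats::rnorm(n))))
  expect_equal(correlate_change(tab, "rnf2", "par_exact")$r2, 1)
  # invariant to rescaling the parameter
  expect_equal(correlate_change(tab, "rnf2", "par_scaled")$r2, 1)
  expect_lt(correlate_change(tab, "rnf2", "par_indep")$r2, 0.03)
})
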