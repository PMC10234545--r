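test_that("column-sum profile reduces the scalogram as stated", {
  mag <- rbind(c(1, 2), c(3, 4))
  expect_identical(scws_profile(mag)$power, c(4, 6))
  expect_identical(scws_profile(mag, n_layers_sum = 1)$power, c(1, 2))
  z <- scws_profile(matrix(0, 3, 5))
  expect_identical(z$power, rep(0, 5))
  expect_identical(z$mean_power, 0)
  expect_error(scws_profile(mag, n_layers_sum = 3), "between 1 and")
})

test_that("above-mean segmentation finds maximal strict runs", {
  s <- segments_above_mean(c(1, 3, 1, 3, 1))  # mean 1.8
  expect_identical(nrow(s), 2L)
  expect_identical(s$p_start, c(1L, 3L))
  expect_identical(s$p_end, c(2L, 4L))
  expect_identical(s$length, c(1L, 1L))
  # constant profile: strict inequality leaves nothing
  expect_identical(nrow(segments_above_mean(rep(2, 10))), 0L)
  # whole-prefix segment has fmid exactly 0.5
  s2 <- segments_above_mean(c(5, 5, 0, 0))
  expect_identical(nrow(s2), 1L)
  expect_identical(s2$p_start, 0L)
  expect_identical(s2$p_end, 2L)
  expect_identical(s2$fmid, 0.5)
  expect_equal(s2$mean_power, 5)
})

test_that("segmentation agrees exactly with the brute-force scan", {
  set.seed(77)
  for (i in 1:100) {
    n <- sample(10:400, 1)
    power <- rexp(n) * sample(c(1, 10), 1)
    got <- segments_above_mean(power)
    ref <- oracle_segments(power)
    expect_identical(got$p_start, as.integer(ref$p_start))
    expect_identical(got$p_end, as.integer(ref$p_end))
  }
})

test_that("fmid follows the corrected-midpoint formula and its bounds", {
  expect_identical(fmid(0, 100), 0.5)
  expect_identical(fmid(50, 100), 0.25)
  expect_identical(fmid(99, 100), 0.005)
  # whole-prefix span is 0.5 for every end coordinate
  for (L in c(1, 2, 10, 1000)) expect_identical(fmid(0, L), 0.5)
  # strictly decreasing in p_start at fixed end
  v <- fmid(0:99, 100)
  expect_true(all(diff(v) < 0))
  expect_true(all(v > 0 & v <= 0.5))
  expect_error(fmid(5, 5), "p_start < p_end")
  expect_error(fmid(-1, 5), "p_start")
})

test_that("the seven wavelet features follow their set definitions", {
  empty <- segments_above_mean(rep(1, 5))
  expect_identical(unname(wavelet_features(empty)), rep(0, 7))

  # two segments, lengths 2 and 4: population variance convention
  p <- c(9, 9, 0, 8, 8, 8, 8, 0, 0, 0, 0, 0)
  segs <- segments_above_mean(p)
  expect_identical(segs$length, c(2L, 4L))
  wf <- wavelet_features(segs)
  expect_identical(unname(wf["Count"]), 2)
  expect_identical(unname(wf["LenMean"]), 3)
  expect_identical(unname(wf["LenVar"]), 1)   # population, not sample
  expect_identical(unname(wavelet_features(segs,
                          variance_mode = "sample")["LenVar"]), 2)

  # six segments with lengths {40,35,31,10,5,2}: top third = {40,35}
  segs6 <- data.frame(
    p_start = c(0L, 100L, 200L, 300L, 400L, 500L),
    p_end = c(40L, 135L, 231L, 310L, 405L, 502L),
    length = c(40L, 35L, 31L, 10L, 5L, 2L),
    mean_power = c(10, 20, 30, 40, 50, 60),
    fmid = fmid(c(0, 100, 200, 300, 400, 500),
                c(40, 135, 231, 310, 405, 502)))
  wf6 <- wavelet_features(segs6)
  expect_identical(unname(wf6["30Count"]), 2)
  expect_equal(unname(wf6["30PwMean"]), mean(c(10, 20)))
  expect_equal(unname(wf6["30LenCount"]), mean(c(40, 35, 31)))
  # literal alternative reading keeps every >30 segment (all > 6/3)
  alt <- wavelet_features(segs6, third_rule = "length_vs_count")
  expect_identical(unname(alt["30Count"]), 3)
})

test_that("features are scale-invariant except the power mean", {
  set.seed(31)
  power <- rexp(300)
  a <- wavelet_features(segments_above_mean(power))
  b <- wavelet_features(segments_above_mean(power * 7))
  expect_equal(a[setdiff(names(a), "30PwMean")],
               b[setdiff(names(b), "30PwMean")])
  if (a[["30PwMean"]] > 0) {
    expect_equal(b[["30PwMean"]], 7 * a[["30PwMean"]])
  }
  # structural invariants on random profiles
  for (i in 1:25) {
    p <- rexp(sample(20:500, 1))
    w <- wavelet_features(segments_above_mean(p))
    expect_true(all(is.finite(w)))
    expect_gte(w[["Count"]], w[["30Count"]])
    if (w[["Count"]] > 0) {
      expect_true(w[["MidMean"]] > 0 && w[["MidMean"]] <= 0.5)
    }
    lens <- segments_above_mean(p)$length
    expect_identical(w[["30LenCount"]] == 0, !any(lens > 30))
  }
})
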