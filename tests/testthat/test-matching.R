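test_that("frame operators agree with brute-force pair counting", {
  set.seed(401)
  for (rep in 1:20) {
    pair <- random_ternary_pair(6, 9)
    w <- match_window(rep(2:7, each = 6), rep(1:6, times = 6), d = 1L)
    l <- pair$left[cbind(w$y, w$x)]
    r <- pair$right[cbind(w$y, w$x - 1L)]
    expect_equal(cross_matching_frame(pair, w), count_matched_fraction(l, r))
    expect_equal(cross_correlation_frame(pair, w), mean(l * r))
    # antisymmetry of C in the right eye's contrast
    flipped <- pair_of(pair$left, -pair$right)
    expect_equal(cross_correlation_frame(flipped, w),
                 -cross_correlation_frame(pair, w))
  }
})

test_that("operator bounds and identities hold on random frames", {
  set.seed(402)
  for (rep in 1:30) {
    pair <- random_ternary_pair(5, 5, p_dot = runif(1))
    w <- full_window(5, 5)
    C <- cross_correlation_frame(pair, w)
    M <- cross_matching_frame(pair, w)
    G <- generalized_cross_matching_frame(pair, w)
    expect_true(abs(C) <= 1)
    expect_true(G >= 0 && G <= M && M <= 1)
    # M - C equals the contrast-reversed pair fraction
    l <- pair$left[cbind(w$y, w$x)]; r <- pair$right[cbind(w$y, w$x)]
    expect_equal(M - C, mean(l != 0 & r == -l))
    # ON/OFF channel form is exactly the cross-matching
    expect_identical(onoff_cross_matching_frame(pair, w), M)
  }
})

test_that("perfectly matched bright window gives correlation 1; anticorrelated gives matching 0", {
  ones <- matrix(1L, 2, 2)
  expect_equal(cross_correlation_frame(pair_of(ones, ones), full_window(2, 2)), 1)
  expect_equal(cross_matching_frame(pair_of(ones, -ones), full_window(2, 2)), 0)
})

test_that("a single-pixel window makes generalized and original cross-matching equal", {
  set.seed(403)
  for (rep in 1:10) {
    pair <- random_ternary_pair(3, 3)
    w <- match_window(2, 2, d = sample(-1:1, 1))
    expect_equal(generalized_cross_matching_frame(pair, w),
                 cross_matching_frame(pair, w))
  }
})

test_that("out-of-bounds windows error instead of being clipped", {
  pair <- random_ternary_pair(4, 4)
  expect_error(cross_correlation_frame(pair, full_window(4, 4, d = 1L)),
               "outside")
  expect_error(cross_matching_frame(pair, match_window(5, 1)), "outside")
  expect_error(match_window(integer(0), integer(0)), "at least one")
})

test_that("tuning curves peak (or trough) at the stimulus disparity", {
  geom <- list(center = 16L, surround = 24L)
  mk_seq <- function(c) frame_sequence(
    rds_spec(geom$center, geom$surround, dot_density = 0.25,
             binocular_correlation = c, stimulus_disparity = -2L),
    n_frames = 300L, seed = 404)
  ds <- -4:4

  tc_c <- tuning_curve(mk_seq(1), "correlation", ds)
  tc_m <- tuning_curve(mk_seq(1), "matching", ds)
  i <- match(-2L, tc_c$disparity)
  expect_equal(which.max(tc_c$value), i)
  expect_equal(which.max(tc_m$value), i)
  expect_lt(abs(tc_c$value[i] - 0.25), 3 * tc_c$se[i])  # C = c*rho at the peak
  expect_lt(abs(tc_m$value[i] - 0.25), 3 * tc_m$se[i])  # M = (1+c)rho/2

  # anticorrelated: correlation inverts, matching is exactly 0 at d = d_s
  tc_ac <- tuning_curve(mk_seq(-1), "correlation", ds)
  expect_equal(which.min(tc_ac$value), i)
  expect_lt(abs(tc_ac$value[i] + 0.25), 3 * tc_ac$se[i])
  tc_am <- tuning_curve(mk_seq(-1), "matching", ds)
  expect_identical(tc_am$value[i], 0)
  expect_true(all(tc_am$value <= 0.25^2 / 2 + 3 * pmax(tc_am$se, 1e-4)))

  # reproducibility from the sequence seed
  expect_identical(tc_c$value, tuning_curve(mk_seq(1), "correlation", ds)$value)
  expect_error(tuning_curve(mk_seq(1), "fancy"), "arg")
})

test_that("frame means converge to the closed-form expectations", {
  set.seed(405)
  out <- stereomatch:::.frame_outputs_cpp(3000L, 16L, 24L, 0.25, 0.5, -2L,
                                          -2L, 2L)
  k <- 256
  se_c <- apply(out, 2, sd) / sqrt(nrow(out))
  expect_lt(abs(mean(out[, 1]) - expected_operator_value("correlation", 0.5, 0.25)),
            3 * se_c[1])
  expect_lt(abs(mean(out[, 2]) - 0), 3 * se_c[2])
  expect_lt(abs(mean(out[, 3]) - expected_operator_value("matching", 0.5, 0.25)),
            3 * se_c[3])
  expect_lt(abs(mean(out[, 4]) - 0.25^2 / 2), 3 * se_c[4])
})

test_that("the batch simulator and the R-level operators share one code path", {
  spec <- rds_spec(dot_density = 0.5, binocular_correlation = 0.3,
                   stimulus_disparity = -2L)
  set.seed(406)
  fast <- stereomatch:::.frame_outputs_cpp(1L, 32L, 34L, 0.5, 0.3, -2L, -2L, 2L)
  set.seed(406)
  pair <- generate_rds(spec)
  expect_identical(
    as.numeric(fast),
    c(cross_correlation_frame(pair, detector_window(-2)),
      cross_correlation_frame(pair, detector_window(2)),
      cross_matching_frame(pair, detector_window(-2)),
      cross_matching_frame(pair, detector_window(2))))
})
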