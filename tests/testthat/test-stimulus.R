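test_that("generated images are ternary and reproducible from the seed", {
  for (params in list(c(0.25, 1), c(0.5, 0), c(1, -1), c(0.75, 0.5))) {
    spec <- rds_spec(dot_density = params[1], binocular_correlation = params[2],
                     seed = 11)
    p1 <- generate_rds(spec)
    p2 <- generate_rds(spec)
    expect_true(all(p1$left %in% -1:1) && all(p1$right %in% -1:1))
    expect_identical(p1$left, p2$left)
    expect_identical(p1$right, p2$right)
    expect_equal(dim(p1$left), c(34L, 34L))
  }
})

test_that("zero density yields blank images; full correlation has no reversed dots", {
  blank <- generate_rds(rds_spec(dot_density = 0, seed = 1))
  expect_true(all(blank$left == 0L) && all(blank$right == 0L))

  spec <- rds_spec(dot_density = 0.25, binocular_correlation = 1,
                   stimulus_disparity = 0L, seed = 2)
  pair <- generate_rds(spec)
  stats <- measure_pair_statistics(pair, detector_window(0))
  expect_identical(stats$match_fraction, 1)
})

test_that("invalid specs are rejected with the violated invariant named", {
  expect_error(rds_spec(dot_density = 1.2), "dot_density")
  expect_error(rds_spec(binocular_correlation = -2), "binocular_correlation")
  expect_error(rds_spec(stimulus_disparity = -5), "stimulus_disparity")
  expect_error(rds_spec(center_size = 40, surround_size = 34), "surround_size")
})

test_that("empirical combination frequencies match the analytic probability vector", {
  # aligned window: ((1+c)rho/2, (1-c)rho/2); far-misaligned: rho^2/2 each.
  # 3-SE Monte-Carlo tolerance at n pixels.
  set.seed(301)
  spec <- rds_spec(center_size = 16L, surround_size = 28L, dot_density = 0.5,
                   binocular_correlation = 0, stimulus_disparity = 0L)
  n_frames <- 400L  # 400 * 256 pixels > 1e5 samples
  k <- 16L^2
  aligned <- detector_window(0, 16L, 28L)
  offset <- detector_window(6L, 16L, 28L)
  n_m <- n_dot <- n_dot_off <- n_m_off <- 0
  for (f in seq_len(n_frames)) {
    pair <- generate_rds(spec)
    s <- measure_pair_statistics(pair, aligned)
    n_dot <- n_dot + s$dotted_fraction * k
    n_m <- n_m + s$dotted_fraction * k * s$match_fraction
    s2 <- measure_pair_statistics(pair, offset)
    n_dot_off <- n_dot_off + s2$dotted_fraction * k
    n_m_off <- n_m_off + s2$dotted_fraction * k * s2$match_fraction
  }
  n_px <- n_frames * k
  p <- combination_probabilities(0, 0.5, at_match = TRUE)
  se <- sqrt(p$p_matched * (1 - p$p_matched) / n_px)
  expect_lt(abs(n_m / n_px - p$p_matched), 3 * se)
  expect_lt(abs((n_dot - n_m) / n_px - p$p_reversed), 3 * se)
  p_off <- combination_probabilities(0, 0.5, at_match = FALSE)
  se_off <- sqrt(p_off$p_matched * (1 - p_off$p_matched) / n_px)
  expect_lt(abs(n_m_off / n_px - p_off$p_matched), 3 * se_off)
  # misaligned window ignores c: dotted fraction ~ rho^2
  expect_lt(abs(n_dot_off / n_px - 0.5^2), 3 * sqrt(0.25 * 0.75 / n_px))
})

test_that("graded anticorrelation produces the expected matched-dot fraction", {
  set.seed(302)
  spec <- rds_spec(dot_density = 0.25, binocular_correlation = 0.5,
                   stimulus_disparity = -2L)
  fracs <- replicate(150, {
    s <- measure_pair_statistics(generate_rds(spec), detector_window(-2))
    c(s$dotted_fraction, s$match_fraction)
  })
  n_dotted <- sum(fracs[1, ]) * 1024
  frac <- sum(fracs[1, ] * fracs[2, ]) / sum(fracs[1, ])
  se <- sqrt(0.75 * 0.25 / n_dotted)
  expect_lt(abs(frac - 0.75), 3 * se)  # (1+c)/2 = 0.75
})

test_that("dot-based RDSs respect correlation, disparity and dot geometry", {
  # full correlation at zero disparity: the eyes are identical
  spec <- dot_rds_spec(dot_density = 1, binocular_correlation = 1,
                       stimulus_disparity = 0L, seed = 5)
  pair <- generate_dot_rds(spec)
  expect_identical(pair$left, pair$right)
  expect_true(all(pair$left %in% -1:1))

  # forced single dot: one uniform-sign square per eye, shifted by the split
  spec1 <- dot_rds_spec(dot_density = 0.25, binocular_correlation = 1,
                        stimulus_disparity = -8L, seed = 6)
  p1 <- generate_dot_rds(spec1, n_dots = 1L)
  expect_lte(sum(p1$left != 0), 64)
  expect_true(length(unique(p1$left[p1$left != 0])) <= 1)
  # right copy is the left copy displaced by -d_s = +8 columns
  sz <- spec1$image_size
  shifted <- matrix(0L, sz, sz)
  shifted[, 9:sz] <- p1$left[, 1:(sz - 8)]
  expect_identical(p1$right, shifted)

  # anticorrelation flips every dot
  spec2 <- dot_rds_spec(dot_density = 0.5, binocular_correlation = -1,
                        stimulus_disparity = 0L, seed = 7)
  p2 <- generate_dot_rds(spec2)
  expect_identical(p2$right, -p2$left)

  expect_error(dot_rds_spec(image_size = 6, dot_size = 8), "dot_size")
})

test_that("pair statistics handle degenerate inputs", {
  blank <- pair_of(matrix(0L, 8, 8), matrix(0L, 8, 8))
  s <- measure_pair_statistics(blank, full_window(8, 8))
  expect_equal(s$dotted_fraction, 0)
  expect_true(is.na(s$match_fraction))

  dense <- generate_rds(rds_spec(dot_density = 1, binocular_correlation = 1,
                                 stimulus_disparity = -2L, seed = 8))
  s2 <- measure_pair_statistics(dense, detector_window(-2))
  expect_equal(s2$dotted_fraction, 1)
  expect_equal(s2$match_fraction, 1)

  expect_error(measure_pair_statistics(blank, full_window(8, 8, d = 3L)),
               "outside")
})
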