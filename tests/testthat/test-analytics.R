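test_that("combination probabilities match the stated vectors and sum to one", {
  expect_equal(unlist(combination_probabilities(1, 0.25, TRUE)),
               c(p_matched = 0.25, p_reversed = 0, p_background = 0.75))
  expect_equal(unlist(combination_probabilities(0.3, 0, TRUE)),
               c(p_matched = 0, p_reversed = 0, p_background = 1))
  expect_equal(unlist(combination_probabilities(0, 0.5, FALSE)),
               c(p_matched = 0.125, p_reversed = 0.125, p_background = 0.75))
  grid <- expand.grid(c = seq(-1, 1, 0.25), rho = seq(0, 1, 0.2),
                      m = c(TRUE, FALSE))
  p <- combination_probabilities(grid$c, grid$rho, grid$m)
  expect_true(all(abs(rowSums(as.matrix(p)) - 1) < 1e-12))
  expect_true(all(as.matrix(p) >= 0))
  expect_error(combination_probabilities(2, 0.5), "correlation")
})

test_that("expected operator values follow the code vectors b and b'", {
  expect_equal(expected_operator_value("correlation", 1, 0.25, TRUE), 0.25)
  expect_equal(expected_operator_value("correlation", 0.7, 0.8, FALSE), 0)
  expect_equal(expected_operator_value("matching", -1, 0.6, TRUE), 0)
  expect_equal(expected_operator_value("matching", 0, 0.25, FALSE), 0.03125)
})

test_that("signal strengths have the documented structure", {
  # S_C = c * rho, odd-symmetric in c
  cg <- seq(-1, 1, 0.25); rg <- seq(0, 1, 0.125)
  g <- expand.grid(c = cg, rho = rg)
  expect_equal(signal_strength_correlation(g$c, g$rho), g$c * g$rho)
  expect_identical(signal_strength_correlation(-g$c, g$rho),
                   -signal_strength_correlation(g$c, g$rho))
  expect_equal(signal_strength_correlation(0.5, 0.25), 0.125)

  # S_M: zero contour on c = rho - 1; c=0 profile peaks at 50% density
  rho <- seq(0, 1, 0.05)
  expect_equal(signal_strength_matching(rho - 1, rho), rep(0, length(rho)))
  expect_equal(signal_strength_matching(0, 0.5), 0.125)
  expect_true(all(signal_strength_matching(0, rho) <= 0.125))
  expect_equal(signal_strength_matching(-1, rho), -rho^2 / 2)
  expect_true(all(diff(signal_strength_matching(-1, rho)) < 0))
})

test_that("trinomial pmf is exact, normalized, and stable for large k", {
  expect_equal(trinomial_pmf(c(5, 0, 0), c(1, 0, 0)), 1)
  expect_equal(trinomial_pmf(c(1, 1, 0), c(0.5, 0.25, 0.25)), 0.25)
  # normalization by enumeration at k = 10
  k <- 10
  counts <- as.matrix(expand.grid(n_m = 0:k, n_r = 0:k))
  counts <- counts[rowSums(counts) <= k, ]
  counts <- cbind(counts, n_b = k - rowSums(counts))
  expect_equal(sum(trinomial_pmf(counts, c(0.2, 0.3, 0.5))), 1)
  # log-space evaluation stays finite at k = 1024
  lp <- trinomial_pmf(c(512, 256, 256), c(0.5, 0.25, 0.25), log = TRUE)
  expect_true(is.finite(lp) && lp < 0)
  expect_error(trinomial_pmf(c(1, 1), c(0.5, 0.5, 0)), "three")
})

test_that("generalized signal strength interpolates between cross-matching and rectified correlation", {
  cg <- seq(-1, 1, 0.25); rg <- seq(0.1, 1, 0.15)
  g <- expand.grid(c = cg, rho = rg)
  # k = 1 reproduces the original cross-matching
  expect_equal(signal_strength_generalized(g$c, g$rho, 1),
               signal_strength_matching(g$c, g$rho), tolerance = 1e-12)
  # k = Inf is the half-wave-rectified cross-correlation
  expect_equal(signal_strength_generalized(g$c, g$rho, Inf),
               pmax(g$c * g$rho, 0))
  expect_equal(signal_strength_generalized(-1, 0.25, Inf), 0)
  # spot value from the k = 2 closed form
  expect_equal(signal_strength_generalized(0, 0.5, 2), 0.078125)
  # convergence toward the k = Inf limit at sampled parameters
  pts <- list(c(0.5, 0.5), c(-0.5, 0.75), c(0, 0.5), c(-1, 0.6))
  for (pr in pts) {
    lim <- signal_strength_generalized(pr[1], pr[2], Inf)
    e8 <- abs(signal_strength_generalized(pr[1], pr[2], 8) - lim)
    e512 <- abs(signal_strength_generalized(pr[1], pr[2], 512) - lim)
    expect_lt(e512, e8)
  }
  expect_error(signal_strength_generalized(0, 0.5, 0), "k must")
})

test_that("operator distributions have correct moments and central intervals", {
  # degenerate stimulus: point mass at zero
  d0 <- operator_distribution("matching", 0.5, 0, 64)
  expect_equal(d0$value[d0$probability > 0.999], 0)
  expect_equal(attr(d0, "interval"), c(0, 0))

  for (model in c("correlation", "matching")) {
    for (prm in list(c(0.5, 0.25, TRUE), c(-0.4, 0.6, FALSE), c(0, 1, TRUE))) {
      d <- operator_distribution(model, prm[1], prm[2], 64, as.logical(prm[3]))
      expect_equal(sum(d$probability), 1, tolerance = 1e-9)
      expect_equal(attr(d, "mean"),
                   expected_operator_value(model, prm[1], prm[2],
                                           as.logical(prm[3])),
                   tolerance = 1e-9)
      iv <- attr(d, "interval")
      expect_gte(sum(d$probability[d$value >= iv[1] & d$value <= iv[2]]), 0.95)
    }
  }
  # binomial SD closed form: matched matching with p_m = 0.5, k = 1024
  d <- operator_distribution("matching", 1, 0.5, 1024)
  expect_equal(attr(d, "sd"), 0.5 / 32, tolerance = 1e-9)
})

test_that("variability surfaces vanish at zero density and scale as 1/sqrt(k)", {
  s0 <- sd_surface(c_grid = c(-1, 0, 1), rho_grid = 0,
                   n_patterns = 50, n_runs = 2, seed = 406)
  expect_true(all(s0$sd == 0))

  s_small <- sd_surface(c_grid = 0, rho_grid = 1, center_size = 16L,
                        surround_size = 18L, n_patterns = 400, n_runs = 10,
                        seed = 407)
  s_big <- sd_surface(c_grid = 0, rho_grid = 1, center_size = 32L,
                      surround_size = 34L, n_patterns = 400, n_runs = 10,
                      seed = 408)
  ratio <- s_small$sd / s_big$sd  # k: 256 vs 1024 -> expect ~2
  expect_true(all(abs(ratio - 2) < 0.25))
})
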