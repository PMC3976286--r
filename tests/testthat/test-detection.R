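# a fixed-stage toy: negligible growth so the primary size stays at one
# cell, metastases present from the start
toy_courses <- function(n, lam = 1e-9) {
  tibble::tibble(id = seq_len(n), onset_age = 50, lambda = lam,
                 t_nodal = 0, t_distant = 0)
}

test_that("mode hazards decompose additively by stage", {
  dp <- detection_params()
  h <- mode_hazards(2, 0, 0, dp)
  expect_equal(h$h_primary, dp$eta * 2 + dp$w0)
  expect_equal(h$h_nodal, 0)
  expect_equal(h$h_distant, 0)
  expect_equal(h$z, h$h_primary)

  h11 <- mode_hazards(2, 1, 1, dp)
  expect_equal(h11$z, dp$eta * 2 + dp$w0 + dp$w1 + dp$w2)
  # ratio of the distant to nodal offsets at the default estimates
  expect_equal(h11$h_distant / h11$h_nodal, 7.00e4 / 1.50e3)
  expect_equal(h11$h_distant / h11$h_nodal, 46.67, tolerance = 1e-3)
  # the metastasis offsets dwarf the primary-route hazard for any size
  # reachable in the binning range
  expect_gt(mode_hazards(100, 1, 1, dp)$z / mode_hazards(100, 0, 0, dp)$z, 100)
  expect_error(mode_hazards(-1, 0, 0, dp), "positive")
})

test_that("zero hazards never detect; an overwhelming offset detects in cycle one", {
  dp0 <- detection_params(eta = 0, w0 = 0, w1 = 0, w2 = 0)
  res <- simulate_detection(toy_courses(200), dp0, censor_age = 90, seed = 1)
  expect_true(!any(res$detected))
  expect_true(all(is.na(res$stage)))

  dp_inf <- detection_params(eta = 0, w0 = 1e9, w1 = 0, w2 = 0)
  far <- dplyr::mutate(toy_courses(200), t_nodal = 1e6, t_distant = 1e6)
  res1 <- simulate_detection(far, dp_inf, censor_age = 90, seed = 1)
  expect_true(all(res1$detected))
  expect_true(all(res1$t_detect == 1))
  expect_true(all(res1$mode == "primary"))
  expect_true(all(res1$stage == "N0M0"))
})

test_that("cycle detection follows the geometric law on a constant-hazard toy", {
  dp <- detection_params(eta = 0, w0 = 0.1, w1 = 0.2, w2 = 0.3)
  n <- 2e4
  res <- simulate_detection(toy_courses(n), dp, censor_age = 1e4, seed = 2)
  z <- 0.1 + 0.2 + 0.3
  p <- 1 - exp(-z)
  expect_true(all(res$detected))
  for (k in 1:4) {
    p_k <- (1 - p)^(k - 1) * p
    emp <- mean(res$t_detect == k)
    expect_lt(abs(emp - p_k), 3 * sqrt(p_k * (1 - p_k) / n))
  }
})

test_that("detection modes occur in proportion to their hazards", {
  dp <- detection_params(eta = 0, w0 = 0.1, w1 = 0.2, w2 = 0.3)
  n <- 2e4
  res <- simulate_detection(toy_courses(n), dp, censor_age = 1e4, seed = 3)
  shares <- c(0.1, 0.2, 0.3) / 0.6
  for (i in seq_along(shares)) {
    m <- c("primary", "nodal", "distant")[i]
    expect_lt(abs(mean(res$mode == m) - shares[i]),
              3 * sqrt(shares[i] * (1 - shares[i]) / n))
  }
  # stage bookkeeping: mets present from onset on this toy
  expect_true(all(res$N == 1 & res$M == 1 & res$stage == "M1"))
})

test_that("stage labels are consistent with the met indicators and mode", {
  cases <- simulate_cases(2e4, balanced_params(), seed = 4)
  expect_true(all(cases$N[cases$mode == "nodal"] == 1))
  expect_true(all(cases$M[cases$mode == "distant"] == 1))
  expect_true(all(cases$stage[cases$M == 1] == "M1"))
  expect_true(all(cases$stage[cases$M == 0 & cases$N == 1] == "NxM0"))
  expect_true(all(cases$stage[cases$M == 0 & cases$N == 0] == "N0M0"))
  # detection never happens after death
  expect_true(all(cases$detection_age <= cases$death_age))
})

test_that("shrinking the cycle converges to the continuous-time exponential", {
  # constant total hazard z = 0.6: detection time should approach Exp(0.6)
  z <- 0.6
  dp_fine <- detection_params(eta = 0, w0 = z, w1 = 0, w2 = 0,
                              cycle_years = 1 / 64)
  far <- dplyr::mutate(toy_courses(2e4), t_nodal = 1e6, t_distant = 1e6)
  res <- simulate_detection(far, dp_fine, censor_age = 1e4, seed = 5)
  for (tt in c(0.5, 1, 2, 4)) {
    p_model <- 1 - exp(-z * tt)
    emp <- mean(res$t_detect <= tt)
    se <- sqrt(p_model * (1 - p_model) / 2e4)
    # discretization bias at cycle h is O(z*h): allow it alongside MC error
    expect_lt(abs(emp - p_model), 3 * se + z / 64)
  }
})

test_that("stage probabilities conditional on size are coherent", {
  pp <- balanced_params()
  out <- stage_probs_given_size(2.5, pp, n = 4e4, seed = 6)
  expect_equal(out$bin_lo, 2)
  expect_true(out$P_N >= 0 && out$P_N <= 1)
  expect_true(out$P_M >= 0 && out$P_M <= 1)
  expect_gt(out$n_cases, 25)
  expect_error(stage_probs_given_size(2.5, pp, n = 200, min_cases = 1e5),
               "increase")
  # no metastasis processes, no metastases at diagnosis
  pp0 <- progression_params(mu_n = 1e-30, mu_m = 1e-30)
  out0 <- stage_probs_given_size(2.5, pp0, n = 2e4, seed = 7)
  expect_equal(out0$P_N, 0)
  expect_equal(out0$P_M, 0)
})

test_that("distant-met prevalence at diagnosis trends upward with tumor size", {
  cases <- simulate_cases(1e5, balanced_params(), seed = 8)
  by_bin <- cases |>
    dplyr::mutate(bin = floor(diameter_cm)) |>
    dplyr::filter(bin >= 1, bin <= 10) |>
    dplyr::group_by(bin) |>
    dplyr::summarize(pm = mean(M), n = dplyr::n())
  fit <- stats::lm(pm ~ bin, data = by_bin, weights = by_bin$n)
  expect_gt(coef(fit)[["bin"]], 0)
})
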