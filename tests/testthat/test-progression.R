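test_that("exponential growth from a single cell", {
  pp <- progression_params()
  expect_equal(cells_at(4, 0), 1)
  expect_equal(volume_at(4, 0, pp), 1e-9)
  expect_equal(cells_at(2.2, log(2) / 2.2), 2)
  expect_equal(cells_at(4.37, 6), exp(26.22))
  expect_error(cells_at(4, -1), "nonnegative")
})

test_that("doubling time conversions match the printed growth rates", {
  # median N0M0 growth rate 6.30/yr corresponds to a 40.15-day doubling time
  expect_equal(doubling_time_days(6.30), 40.15, tolerance = 1e-3)
  expect_equal(doubling_time_days(365 * log(2)), 1)
  # the mean growth rate K*theta = 4.37 implies a doubling time in 55-60 d
  pp <- progression_params()
  dt <- doubling_time_days(pp$K * pp$theta)
  expect_gt(dt, 55)
  expect_lt(dt, 60)
  expect_error(doubling_time_days(0))
})

test_that("sphere conversions are mutually inverse and match printed medians", {
  expect_equal(round(diameter_from_volume(0.06), 2), 0.49)
  expect_equal(round(diameter_from_volume(0.16), 2), 0.67)
  v <- c(1e-6, 0.06, 3.5, 900)
  expect_equal(volume_from_diameter(diameter_from_volume(v)), v,
               tolerance = 1e-12)
  expect_error(diameter_from_volume(-1))
  expect_error(volume_from_diameter(0))
})

test_that("detached-cell count follows xi * (e^(lambda t) - 1)", {
  expect_equal(detached_cells(3, 0.01, 0), 0)
  lam <- 2.5
  expect_equal(detached_cells(lam, 0.01, log(2) / lam), 0.01)
  t <- seq(0.1, 10, by = 0.5)
  expect_true(all(detached_cells(lam, 1, t) < cells_at(lam, t)))
})

test_that("metastasis c.d.f. has the closed form and c.d.f. properties", {
  pp <- progression_params()
  lam <- 4.4
  expect_equal(met_cdf(lam, pp, 0, "nodal"), 0)
  t <- seq(0, 25, by = 0.25)
  Fn <- met_cdf(lam, pp, t, "nodal")
  expect_true(all(diff(Fn) >= 0))
  expect_gt(met_cdf(lam, pp, 60, "nodal"), 1 - 1e-10)
  # hazard integrates to the cumulative hazard implied by the c.d.f.
  H <- integrate(function(u) met_hazard(lam, pp, u, "nodal"), 0, 8)$value
  expect_equal(exp(-H), 1 - met_cdf(lam, pp, 8, "nodal"), tolerance = 1e-6)
})

test_that("metastasis c.d.f. matches a thinned-Poisson first-event oracle", {
  # cell-count units with an inflated rate so events land within decades
  pp <- progression_params(xi = 0.5, mu_n = 2e-3, mu_m = 1e-3,
                           met_size_unit = "cells")
  lam <- 0.7
  set.seed(505)
  n_rep <- 2000
  times <- mc_first_event_times(n_rep, lam, rate0 = pp$mu_n * pp$xi)
  for (tt in c(6, 9, 12)) {
    p_emp <- mean(times <= tt)
    p_model <- met_cdf(lam, pp, tt, "nodal")
    se <- sqrt(p_model * (1 - p_model) / n_rep)
    expect_lt(abs(p_emp - p_model), 3 * se)
  }
})

test_that("sampled metastasis times invert the c.d.f. and are ordered in law", {
  pp <- progression_params()
  lam <- rep(3.5, 1e5)
  mets <- sample_met_times(lam, pp, seed = 21)
  for (tt in c(4, 6, 9)) {
    for (site in c("nodal", "distant")) {
      col <- if (site == "nodal") mets$t_nodal else mets$t_distant
      p_model <- met_cdf(3.5, pp, tt, site)
      se <- sqrt(p_model * (1 - p_model) / 1e5)
      expect_lt(abs(mean(col <= tt) - p_model), 3 * se)
    }
    # mu_n >= mu_m: nodal metastases come first stochastically
    expect_gte(mean(mets$t_nodal <= tt), mean(mets$t_distant <= tt))
    expect_gte(met_cdf(3.5, pp, tt, "nodal"), met_cdf(3.5, pp, tt, "distant"))
  }
  expect_identical(mets, sample_met_times(lam, pp, seed = 21))
})

test_that("growth-rate draws recover the gamma mean and variance", {
  pp <- progression_params()
  lam <- sample_growth_rates(1e5, pp, seed = 31)
  m <- pp$K * pp$theta
  v <- pp$K * pp$theta^2
  # SEs of the sample mean and variance of a gamma distribution
  se_mean <- sqrt(v / 1e5)
  se_var <- sqrt((2 + 6 / pp$K) * v^2 / 1e5)
  expect_lt(abs(mean(lam) - m), 3 * se_mean)
  expect_lt(abs(var(lam) - v), 3 * se_var)
})

test_that("marginal metastasis densities are normalized and nonnegative", {
  for (pp in list(progression_params(),
                  progression_params(xi = 0.5, mu_n = 2e-3, mu_m = 1e-3,
                                     met_size_unit = "cells"))) {
    for (site in c("nodal", "distant")) {
      f <- function(t) marginal_met_pdf(pp, t, site)
      expect_true(all(f(c(1, 5, 20)) >= 0))
      total <- integrate(f, 0, Inf, rel.tol = 1e-6)$value
      expect_lt(abs(total - 1), 1e-3)
    }
  }
})

test_that("a degenerate growth-rate distribution collapses the marginal mode to the conditional one", {
  c0 <- 4
  pp <- progression_params(K = 4000, theta = c0 / 4000)
  kappa <- pp$cell_volume * 1e3
  t_cond <- log(1 / (pp$mu_n * pp$xi * kappa)) / c0
  expect_equal(marginal_met_mode(pp, "nodal", interval = c(1, 15)), t_cond,
               tolerance = 0.02)
})

test_that("nodal-only density is dominated by the marginal nodal density", {
  pp <- progression_params()
  t <- c(1, 3, 5, 7, 10, 15)
  expect_true(all(nodal_only_pdf(pp, t) <=
                    marginal_met_pdf(pp, t, "nodal") + 1e-12))
  # with a negligible distant process the two coincide
  pp0 <- progression_params(mu_n = 8.05e-9, mu_m = 1e-25)
  expect_equal(nodal_only_pdf(pp0, t), marginal_met_pdf(pp0, t, "nodal"),
               tolerance = 1e-8)
})

test_that("nodal-only density matches a simulation estimate", {
  pp <- progression_params()
  lam <- sample_growth_rates(2e5, pp, seed = 41)
  mets <- sample_met_times(lam, pp, seed = 42)
  breaks <- c(2, 4, 6, 8)
  for (i in seq_len(length(breaks) - 1)) {
    lo <- breaks[i]; hi <- breaks[i + 1]
    p_emp <- mean(mets$t_nodal >= lo & mets$t_nodal < hi &
                    mets$t_distant >= mets$t_nodal)
    p_model <- integrate(function(t) nodal_only_pdf(pp, t), lo, hi,
                         rel.tol = 1e-6)$value
    se <- sqrt(p_model * (1 - p_model) / 2e5)
    expect_lt(abs(p_emp - p_model), 3 * se)
  }
})
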