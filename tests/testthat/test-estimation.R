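test_that("histogramming cases matches a direct recount", {
  cases <- simulate_cases(5000, balanced_params(), seed = 11)
  tab <- histogram_cases(cases)
  expect_s3_class(tab, "size_stage_table")
  expect_equal(nrow(tab), 60)
  expect_equal(sum(tab$prop), 1)
  expect_equal(attr(tab, "n_cases"), nrow(cases))
  # brute-force recount over records, cell by cell
  for (i in sample(nrow(tab), 12)) {
    st <- tab$stage[i]; lo <- tab$bin_lo[i]
    manual <- sum(cases$stage == st &
                    (pmin(floor(cases$diameter_cm), 19) == lo)) / nrow(cases)
    expect_equal(tab$prop[i], manual)
  }
  expect_error(histogram_cases(cases[0, ]), "empty")
})

test_that("a single case concentrates all mass in its cell", {
  one <- tibble::tibble(stage = "N0M0", diameter_cm = 2.5)
  tab <- histogram_cases(one)
  expect_equal(tab$prop[tab$stage == "N0M0" & tab$bin_lo == 2], 1)
  expect_equal(sum(tab$prop), 1)
  # oversized tumors are lumped into the last bin
  big <- tibble::tibble(stage = "M1", diameter_cm = 57)
  expect_equal(histogram_cases(big)$prop[60], 1)
})

test_that("the least-squares objective matches a brute-force double loop", {
  set.seed(12)
  mk <- function() {
    p <- runif(60)
    new_size_stage_table(dplyr::mutate(size_stage_grid_tbl(), prop = p / sum(p)))
  }
  size_stage_grid_tbl <- function() {
    tidyr::expand_grid(stage = c("N0M0", "NxM0", "M1"), bin_lo = 0:19) |>
      dplyr::mutate(bin_hi = bin_lo + 1)
  }
  a <- mk(); b <- mk()
  brute <- 0
  for (st in c("N0M0", "NxM0", "M1")) {
    for (j in 0:19) {
      pa <- a$prop[a$stage == st & a$bin_lo == j]
      pb <- b$prop[b$stage == st & b$bin_lo == j]
      brute <- brute + (pa - pb)^2
    }
  }
  expect_equal(least_squares(a, b), brute, tolerance = 1e-14)
  expect_equal(least_squares(a, b), least_squares(b, a))
  expect_equal(least_squares(a, a), 0)
})

test_that("tables concentrated in disjoint cells are at squared distance 2", {
  base <- tidyr::expand_grid(stage = c("N0M0", "NxM0", "M1"), bin_lo = 0:19) |>
    dplyr::mutate(bin_hi = bin_lo + 1, prop = 0)
  a <- dplyr::mutate(base, prop = as.numeric(stage == "N0M0" & bin_lo == 1))
  b <- dplyr::mutate(base, prop = as.numeric(stage == "M1" & bin_lo == 7))
  expect_equal(least_squares(new_size_stage_table(a),
                             new_size_stage_table(b)), 2)
})

test_that("table validation rejects malformed input", {
  bad <- tidyr::expand_grid(stage = c("N0M0", "NxM0", "M1"), bin_lo = 0:19) |>
    dplyr::mutate(bin_hi = bin_lo + 1, prop = 1) # sums to 60
  expect_error(new_size_stage_table(bad), "sum to 1")
  tab <- make_fixture_table(n = 500, seed = 13)
  short <- new_size_stage_table(
    dplyr::mutate(tibble::as_tibble(tab)[1:30, ],
                  prop = prop / sum(prop)))
  expect_error(least_squares(tab, short), "mismatch")
})

test_that("the objective is reproducible under common random numbers", {
  a <- make_fixture_table(n = 2000, seed = 14)
  b <- make_fixture_table(n = 2000, seed = 14)
  expect_identical(a$prop, b$prop)
})

test_that("initializing at the truth stays at the truth", {
  pp <- progression_params(); dp <- detection_params()
  obs <- make_fixture_table(pp, dp, n = 2e4, seed = 15)
  fit <- fit_size_stage(obs, pp, dp,
                        options = fit_options(n_sim = 1e4, maxit = 60))
  # loss at/near the Monte-Carlo noise floor, and no drift beyond the
  # initial simplex scale
  expect_lt(fit$loss, 5e-3)
  est <- tidy(fit)$estimate
  truth <- c(pp$xi, pp$mu_n, pp$mu_m, pp$K, pp$theta,
             dp$eta, dp$w0, dp$w1, dp$w2)
  expect_true(all(abs(log(est / truth)) < log(2.2)))
  expect_s3_class(glance(fit), "tbl_df")
  expect_equal(glance(fit)$n_obs_cases, attr(obs, "n_cases"))
})

test_that("bootstrap intervals respect bounds and bracket the estimate", {
  pp <- progression_params(); dp <- detection_params()
  obs <- make_fixture_table(pp, dp, n = 1e4, seed = 16)
  fit <- fit_size_stage(obs, pp, dp,
                        options = fit_options(n_sim = 5e3, maxit = 15))
  expect_warning(
    ci <- bootstrap_ci(obs, fit, B = 2,
                       options = fit_options(n_sim = 5e3, maxit = 10),
                       seed = 17),
    "unstable")
  expect_equal(nrow(ci), 9)
  expect_true(all(ci$lower <= ci$upper))
  expect_true(all(ci$lower > 0))
  mu <- dplyr::filter(tidy(fit, ci = ci), term %in% c("mu_n", "mu_m"))
  expect_true(all(is.finite(mu$lower)))
  xi_ci <- dplyr::filter(ci, term == "xi")
  # xi is profiled at its initial value, so its interval is degenerate there
  expect_equal(xi_ci$lower, fit$pp$xi)
  expect_equal(xi_ci$upper, fit$pp$xi)
  expect_error(bootstrap_ci(obs, fit, B = 1), "at least 2")
})
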