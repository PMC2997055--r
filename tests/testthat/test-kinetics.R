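test_that("forward rate law matches closed forms and saturates below k_r", {
  expect_identical(kobs_from_conc(0, obi), 0)
  # half-maximal rate at conc = K_D, both built-in constant sets
  expect_equal(kobs_from_conc(32.20, obi), 0.405)
  expect_equal(kobs_from_conc(50.10, hi6), 0.3385)
  expect_equal(kobs_from_conc(10, hi6), 0.677 * 10 / 60.10)

  conc <- 10^seq(-3, 6, length.out = 200)
  k <- kobs_from_conc(conc, obi)
  expect_true(all(diff(k) > 0))         # strictly increasing
  expect_true(all(k < obi$k_r))         # bounded by the ceiling

  expect_error(kobs_from_conc(-1, obi), class = "oxitrans_domain_error")
})

test_that("concentration inversion is the exact inverse of the rate law", {
  expect_identical(conc_from_kobs(0, obi), 0)
  expect_equal(conc_from_kobs(0.405, obi), 32.20)  # half-maximal rate -> K_D
  expect_equal(conc_from_kobs(0.2, obi), 32.20 * 0.2 / (0.81 - 0.2))
  expect_equal(kobs_from_conc(conc_from_kobs(0.2, obi), obi), 0.2, tolerance = 1e-12)

  for (pair in list(obi, hi6)) {
    conc <- 10^seq(-3, 4, length.out = 400)
    back <- conc_from_kobs(kobs_from_conc(conc, pair), pair)
    expect_lt(max(abs(back - conc) / conc), 1e-9)
  }

  expect_error(conc_from_kobs(obi$k_r, obi), class = "oxitrans_saturation_error")
  expect_error(conc_from_kobs(1.5 * obi$k_r, obi), class = "oxitrans_saturation_error")
  expect_error(conc_from_kobs(-0.1, obi), class = "oxitrans_domain_error")
  # just below the ceiling still resolves
  expect_true(is.finite(conc_from_kobs(obi$k_r * (1 - 1e-9), obi)))
})

test_that("reactivated fraction follows monoexponential recovery", {
  expect_identical(reactivation_fraction(0, 60), 0)
  expect_identical(reactivation_fraction(0.3, 0), 0)
  expect_equal(reactivation_fraction(log(2) / 15, 15), 0.5)  # half-life identity
  expect_equal(reactivation_fraction(0.405, 15), 1 - exp(-6.075))

  set.seed(11)
  for (i in 1:20) {
    k <- sort(runif(2, 0, 1))
    t <- sort(runif(2, 0, 120))
    # nondecreasing in t and in kobs
    expect_gte(reactivation_fraction(k[1], t[2]), reactivation_fraction(k[1], t[1]))
    expect_gte(reactivation_fraction(k[2], t[1]), reactivation_fraction(k[1], t[1]))
    expect_lte(reactivation_fraction(k[2], t[2]), 1)
  }
  expect_error(reactivation_fraction(-0.1, 10), class = "oxitrans_domain_error")
  expect_error(reactivation_fraction(0.1, -10), class = "oxitrans_domain_error")
})

test_that("predicted velocity interpolates between the measured baselines", {
  expect_equal(reactivation_velocity(5, 0, v_c = 1.0, v_i = 0.1), 0.1)
  expect_equal(reactivation_velocity(1e6, 15, v_c = 1.0, v_i = 0.1), 1.0)
  expect_equal(reactivation_velocity(log(2) / 15, 15, v_c = 1.0, v_i = 0.2), 0.6)
  expect_error(reactivation_velocity(0.1, 15, v_c = 0.1, v_i = 0.1),
               class = "oxitrans_degenerate_assay_error")
  expect_error(reactivation_velocity(0.1, 15, v_c = 0.05, v_i = 0.1),
               class = "oxitrans_degenerate_assay_error")
})

test_that("least-squares fit recovers generating rates from noiseless data", {
  for (k in c(0.01, 0.05, 0.1, 0.3, 0.6)) {
    fit <- fit_kobs(make_timecourse(k), obi, v_c = 1, v_i = 0.1)
    expect_lt(abs(fit$kobs - k), 1e-6)
    expect_false(fit$censored_high)
  }
  # chained inversion: closed-form check through the concentration scale
  fit <- fit_kobs(make_timecourse(0.25), obi, v_c = 1, v_i = 0.1)
  expect_equal(conc_from_kobs(fit$kobs, obi), 32.20 * 0.25 / 0.56, tolerance = 1e-5)
})

test_that("degenerate time courses fit to zero or censor, with flags", {
  flat <- tibble::tibble(t = default_grid, v_t = rep(0.1, 4))
  fit <- fit_kobs(flat, obi, v_c = 1, v_i = 0.1)
  expect_identical(fit$kobs, 0)

  below <- tibble::tibble(t = default_grid, v_t = c(0.09, 0.08, 0.095, 0.07))
  fit <- fit_kobs(below, obi, v_c = 1, v_i = 0.1)
  expect_identical(fit$kobs, 0)
  expect_true(fit$negative_fractions)

  instant <- tibble::tibble(t = default_grid, v_t = rep(1, 4))
  fit <- fit_kobs(instant, obi, v_c = 1, v_i = 0.1)
  expect_true(fit$censored_high)

  expect_error(fit_kobs(flat, obi, v_c = 0.1, v_i = 0.1),
               class = "oxitrans_degenerate_assay_error")
  expect_error(fit_kobs(flat[1, ], obi, v_c = 1, v_i = 0.1),
               class = "oxitrans_domain_error")
  expect_error(fit_kobs(tibble::tibble(t = c(30, 15), v_t = c(0.5, 0.4)),
                        obi, v_c = 1, v_i = 0.1),
               class = "oxitrans_domain_error")
})

test_that("fit agrees with a brute-force grid search on random instances", {
  set.seed(301)
  k_grid <- seq(0, 0.999 * obi$k_r, by = 1e-5)
  t <- default_grid
  for (i in 1:5) {
    k_true <- round(runif(1, 0.01, 0.6), 5)  # representable on the search grid
    tc <- make_timecourse(k_true, t = t, v_c = 1, v_i = 0.1)
    # vectorised exhaustive search over the rate grid
    resid <- outer(k_grid, t, function(k, t) 0.1 + 0.9 * (1 - exp(-k * t)))
    ssr <- rowSums(sweep(resid, 2, tc$v_t)^2)
    k_brute <- k_grid[which.min(ssr)]
    fit <- fit_kobs(tc, obi, v_c = 1, v_i = 0.1)
    expect_lt(abs(fit$kobs - k_brute), 1e-6)
  }
})

test_that("rate recovery under 5% velocity noise stays within tolerance", {
  set.seed(99)
  errs <- purrr::map(c(0.02, 0.05, 0.1, 0.2, 0.3), function(k) {
    rel <- replicate(200, {
      vt <- reactivation_velocity(k, default_grid, 1, 0.05) *
        (1 + rnorm(4, 0, 0.05))
      fit <- fit_kobs(tibble::tibble(t = default_grid, v_t = vt), obi,
                      v_c = 1, v_i = 0.05)
      (fit$kobs - k) / k
    })
    tibble::tibble(k = k, bias = median(rel), spread = stats::IQR(abs(rel)),
                   med_abs = median(abs(rel)), rel = list(rel))
  }) |> dplyr::bind_rows()
  # bias/spread recorded per rate; the asserted threshold is the pooled median
  expect_true(all(is.finite(errs$bias)))
  pooled <- median(abs(unlist(errs$rel)))
  expect_lt(pooled, 0.15)
})

test_that("tidy, glance and predict expose the fit", {
  fit <- fit_kobs(make_timecourse(0.05), obi, v_c = 1, v_i = 0.1)
  td <- generics::tidy(fit)
  expect_equal(td$estimate, fit$kobs)
  gl <- generics::glance(fit)
  expect_named(gl, c("kobs", "residual_sum_squares", "n_points", "converged",
                     "censored_high", "negative_fractions"))
  expect_equal(predict(fit, 0), 0.1)
  p <- ggplot2::autoplot(fit)
  expect_s3_class(p, "ggplot")
})
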