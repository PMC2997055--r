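test_that("dilution standardization is the cuvette volume ratio, and linear", {
  expect_equal(standardize_concentration(10, dilution_scheme(750, 750)), 10)
  expect_equal(standardize_concentration(2.5, dilution_scheme(500, 1000)), 5)
  expect_equal(standardize_concentration(1.2, dilution_scheme(750, 3000)), 4.8)

  sch <- dilution_scheme(750, 3060)
  set.seed(5)
  c0 <- runif(20, 0, 50)
  a <- runif(20, 0.1, 10)
  expect_equal(standardize_concentration(a * c0, sch),
               a * standardize_concentration(c0, sch))

  # the Transwell leg is a separate factor, default 1
  expect_equal(standardization_factor(dilution_scheme(750, 3000, transwell_factor = 2)), 8)

  expect_error(dilution_scheme(750), class = "oxitrans_config_error")      # no total
  expect_error(dilution_scheme(750, 500), class = "oxitrans_config_error") # total < sample
  expect_error(dilution_scheme(-1, 100), class = "oxitrans_config_error")
  expect_error(standardize_concentration(-1, sch), class = "oxitrans_domain_error")
})

test_that("transport difference is the signed percent change versus free drug", {
  expect_equal(transport_difference(15.06, 10.83), 39.06, tolerance = 1e-3)
  expect_equal(transport_difference(25.91, 8.82), 193.76, tolerance = 1e-4)
  expect_identical(transport_difference(10, 10), 0)
  expect_lt(transport_difference(5, 10), 0)
  expect_gt(transport_difference(15, 10), 0)
  expect_error(transport_difference(10, 0), class = "oxitrans_undefined_reference_error")
  expect_error(transport_difference(-1, 10), class = "oxitrans_domain_error")
})

make_condition <- function(true_conc, pair, scheme, id = "c1",
                           carrier = "free", load = 0.52, dose = 100,
                           v_c = 1, v_i = 0.05) {
  cuvette <- true_conc / standardization_factor(scheme)
  k <- kobs_from_conc(cuvette, pair)
  list(
    tc = tibble::tibble(
      condition_id = id, carrier = carrier, particle_load_mg_cm2 = load,
      loading_dose_uM = dose, replicate_id = "r1", t_min = default_grid,
      v_t = reactivation_velocity(k, default_grid, v_c, v_i)),
    bl = tibble::tibble(condition_id = id, replicate_id = "r1", v_c = v_c, v_i = v_i)
  )
}

test_that("quantification chain recovers known concentrations end to end", {
  ident <- dilution_scheme(750, 750)
  cnd <- make_condition(20, obi, ident)
  rec <- quantify_transport(cnd$tc, cnd$bl, obi, ident)
  expect_equal(rec$standardized_conc_uM, 20, tolerance = 5e-4)
  expect_false(rec$censored)
  expect_equal(rec$carrier, "free")

  # flat-at-baseline time course quantifies to zero
  flat <- cnd
  flat$tc$v_t <- 0.05
  rec0 <- quantify_transport(flat$tc, flat$bl, obi, ident)
  expect_identical(rec0$standardized_conc_uM, 0)

  # realistic cuvette dilution: 39.51 uM transported, 750 ul in 3060 ul
  sch <- dilution_scheme(750, 3060)
  cnd <- make_condition(39.51, obi, sch)
  rec <- quantify_transport(cnd$tc, cnd$bl, obi, sch)
  expect_equal(rec$standardized_conc_uM, 39.51, tolerance = 1e-4)
})

test_that("saturating concentrations censor instead of returning numbers", {
  ident <- dilution_scheme(750, 750)
  for (mult in c(50, 80)) {
    cnd <- make_condition(mult * obi$K_D, obi, ident)
    rec <- quantify_transport(cnd$tc, cnd$bl, obi, ident)
    expect_true(rec$censored)
    expect_true(is.na(rec$standardized_conc_uM))
  }
  # just under the threshold still quantifies
  cnd <- make_condition(49 * obi$K_D, obi, ident)
  rec <- quantify_transport(cnd$tc, cnd$bl, obi, ident)
  expect_false(rec$censored)
  expect_equal(rec$standardized_conc_uM, 49 * obi$K_D, tolerance = 1e-3)
})

test_that("quantification errors carry the stage and condition id", {
  ident <- dilution_scheme(750, 750)
  cnd <- make_condition(20, obi, ident, id = "bad-assay")
  cnd$bl$v_c <- 0.01  # below v_i: degenerate assay
  err <- expect_error(quantify_transport(cnd$tc, cnd$bl, obi, ident),
                      class = "oxitrans_stage_error")
  expect_match(conditionMessage(err), "fit_kobs")
  expect_match(conditionMessage(err), "bad-assay")

  cnd <- make_condition(20, obi, ident)
  expect_error(quantify_transport(cnd$tc, cnd$bl[0, ], obi, ident),
               class = "oxitrans_io_error")
})

test_that("report reproduces the self-consistent printed difference cells", {
  cells <- consistent_diff_cells()
  for (tid in 1:3) {
    rep <- transport_report(transport_reference(tid))
    want <- cells[cells$table_id == tid, ]
    got <- dplyr::left_join(
      want, as.data.frame(rep),
      by = c("carrier", "particle_load_mg_cm2", "loading_dose_uM"))
    expect_lt(max(abs(got$diff_ratio_means_pct - got$printed_diff)), 0.01001)
  }
})

test_that("report ordering, references and conventions behave", {
  rep <- transport_report(transport_reference(1))
  grp <- unique(rep[, c("particle_load_mg_cm2", "loading_dose_uM")])
  expect_equal(grp$particle_load_mg_cm2, c(0.52, 0.52, 0.26, 0.26))
  expect_equal(grp$loading_dose_uM, c(100, 1000, 100, 1000))
  expect_true(all(is.na(rep$transport_difference_pct[rep$carrier == "free"])))

  # equal concentrations give identically zero differences
  eq <- tibble::tibble(
    carrier = c("NP-ApoE", "NP-PEG", "free"),
    particle_load_mg_cm2 = 0.52, loading_dose_uM = 100,
    standardized_conc_uM = 7.7)
  rep_eq <- transport_report(eq)
  expect_equal(rep_eq$diff_ratio_means_pct[rep_eq$carrier != "free"], c(0, 0))

  # a group without its free-drug reference is a hard error naming the group
  no_ref <- transport_reference(1) |> dplyr::filter(carrier != "free" |
                                                    loading_dose_uM != 1000)
  err <- expect_error(transport_report(no_ref), class = "oxitrans_report_error")
  expect_match(conditionMessage(err), "1000")

  # replicated records: ratio-of-means vs mean per-replicate difference
  recs <- tibble::tibble(
    carrier = rep(c("NP-ApoE", "free"), each = 2),
    particle_load_mg_cm2 = 0.52, loading_dose_uM = 100,
    replicate_id = rep(c("r1", "r2"), 2),
    standardized_conc_uM = c(20, 10, 10, 40))
  rep2 <- transport_report(recs, convention = "per-replicate")
  apoe <- rep2[rep2$carrier == "NP-ApoE", ]
  expect_equal(apoe$diff_ratio_means_pct, 100 * (15 / 25 - 1))
  expect_equal(apoe$diff_per_replicate_pct, mean(c(100, -75)))
  expect_equal(apoe$transport_difference_pct, apoe$diff_per_replicate_pct)

  # censored records are dropped from means, loudly
  cen <- transport_reference(1)
  cen$censored <- c(TRUE, rep(FALSE, 11))
  expect_warning(transport_report(cen), "censored")
})

test_that("carrier comparison wraps the exact test with group filters", {
  recs <- tibble::tibble(
    carrier = rep(c("NP-ApoE", "free"), each = 3),
    particle_load_mg_cm2 = 0.26, loading_dose_uM = 1000,
    replicate_id = rep(paste0("r", 1:3), 2),
    standardized_conc_uM = c(41, 44, 39, 15, 19, 17))
  cmp <- compare_transport(recs, "NP-ApoE", "free",
                           particle_load_mg_cm2 = 0.26, loading_dose_uM = 1000)
  expect_equal(cmp$u_statistic, 9)          # complete separation
  expect_equal(cmp$p_value, 0.1)
  expect_false(cmp$approximate)
})
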