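#' Quantify transported oxime from Ellman time courses
#'
#' The full biosensor inference chain, applied per replicate time course:
#' fit the observed reactivation rate ([fit_kobs()]), invert it to the oxime
#' concentration in the cuvette ([conc_from_kobs()]), and standardize for
#' dilution ([standardize_concentration()]).
#'
#' Censoring: a fitted rate at the search ceiling, or one implying a cuvette
#' concentration at or above `conc_max` (default `50 * K_D`, where the
#' hyperbolic rate law retains under 2% of its dynamic range), yields a
#' censored record — `standardized_conc_uM = NA` with `censored = TRUE` —
#' rather than a finite but meaningless number. A rate at or above `k_r`
#' (formally outside the rate law's range) is likewise censored.
#'
#' @param timecourses Data frame, one row per velocity measurement, with
#'   columns `condition_id`, `replicate_id`, `t_min`, `v_t`, and optionally
#'   the metadata columns `carrier`, `particle_load_mg_cm2`,
#'   `loading_dose_uM` (carried through to the output).
#' @param baselines Data frame with columns `condition_id`, `replicate_id`,
#'   `v_c`, `v_i` (one row per replicate; `replicate_id` may be omitted to
#'   share baselines across a condition's replicates).
#' @param pair [oxime_pair] (or standard-pair name).
#' @param scheme [dilution_scheme].
#' @param conc_max Censoring threshold on the cuvette concentration, µM.
#'   Default `50 * K_D`.
#' @return A tibble of transport records, one row per condition × replicate:
#'   metadata, `kobs`, `residual_sum_squares`, `converged`, `censored`,
#'   `cuvette_conc_uM`, `standardized_conc_uM`.
#' @examples
#' obi <- standard_oxime_pair("obidoxime-paraoxon")
#' sch <- dilution_scheme(cuvette_total_ul = 750)  # identity dilution
#' tc <- tibble::tibble(condition_id = "c1", replicate_id = "r1",
#'                      t_min = c(15, 30, 45, 60),
#'                      v_t = reactivation_velocity(
#'                        kobs_from_conc(20, obi), c(15, 30, 45, 60), 1, 0.05))
#' bl <- tibble::tibble(condition_id = "c1", replicate_id = "r1",
#'                      v_c = 1, v_i = 0.05)
#' quantify_transport(tc, bl, obi, sch)
#' @export
quantify_transport <- function(timecourses, baselines, pair, scheme,
                               conc_max = NULL) {
  pair <- as_oxime_pair(pair)
  if (!inherits(scheme, "dilution_scheme")) {
    stop_oxitrans("`scheme` must be a dilution_scheme.", "config")
  }
  conc_max <- conc_max %||% (50 * pair$K_D)
  need_tc <- c("condition_id", "replicate_id", "t_min", "v_t")
  if (!is.data.frame(timecourses) || !all(need_tc %in% names(timecourses))) {
    stop_oxitrans(paste0("`timecourses` must contain columns ",
                         paste(need_tc, collapse = ", "), "."), "io")
  }
  if (!is.data.frame(baselines) || !all(c("condition_id", "v_c", "v_i") %in% names(baselines))) {
    stop_oxitrans("`baselines` must contain columns condition_id, v_c, v_i.", "io")
  }
  by_rep <- "replicate_id" %in% names(baselines)

  meta_cols <- intersect(c("carrier", "particle_load_mg_cm2", "loading_dose_uM"),
                         names(timecourses))

  grouped <- timecourses |>
    dplyr::select(dplyr::all_of(c("condition_id", "replicate_id", meta_cols, "t_min", "v_t"))) |>
    tidyr::nest(points = dplyr::all_of(c("t_min", "v_t")),
                .by = dplyr::all_of(c("condition_id", "replicate_id", meta_cols))) |>
    dplyr::mutate(points = purrr::map(.data$points, ~ dplyr::arrange(.x, .data$t_min)))

  keys <- if (by_rep) c("condition_id", "replicate_id") else "condition_id"
  grouped <- dplyr::left_join(grouped, baselines[, c(keys, "v_c", "v_i")], by = keys)
  missing_bl <- is.na(grouped$v_c) | is.na(grouped$v_i)
  if (any(missing_bl)) {
    bad <- grouped$condition_id[missing_bl][1]
    stop_oxitrans(sprintf(
      "Baseline linkage error: no v_c/v_i entry for condition '%s'%s.",
      bad,
      if (by_rep) sprintf(" replicate '%s'", grouped$replicate_id[missing_bl][1]) else ""),
      "io")
  }

  fits <- purrr::pmap(
    list(grouped$points, grouped$v_c, grouped$v_i, grouped$condition_id),
    function(points, v_c, v_i, id) {
      fit <- tryCatch(
        fit_kobs(dplyr::rename(points, t = "t_min"), pair,
                 v_c = v_c, v_i = v_i, condition_id = id),
        error = function(e) {
          stop_oxitrans(sprintf("Stage fit_kobs failed for condition '%s': %s",
                                id, conditionMessage(e)), "stage")
        }
      )
      censored <- fit$censored_high || fit$kobs >= pair$k_r
      cuvette <- if (censored) NA_real_ else conc_from_kobs(fit$kobs, pair)
      # small numerical slack so a fitted rate within solver tolerance of the
      # censoring concentration is censored, not reported as a boundary value
      if (!censored && cuvette >= conc_max * (1 - 1e-6)) {
        censored <- TRUE
        cuvette <- NA_real_
      }
      tibble(
        kobs = fit$kobs,
        residual_sum_squares = fit$residual_sum_squares,
        converged = fit$converged,
        censored = censored,
        cuvette_conc_uM = cuvette,
        standardized_conc_uM = if (censored) NA_real_
                               else standardize_concentration(cuvette, scheme)
      )
    }
  )

  dplyr::bind_cols(
    grouped[, c("condition_id", meta_cols, "replicate_id")],
    dplyr::bind_rows(fits)
  )
}
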