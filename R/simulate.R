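#' Configure a synthetic Transwell transport experiment
#'
#' Bundles everything the generator needs: the kinetic pair, the design
#' (conditions with their hidden true basolateral concentrations), the
#' dilution scheme, the Ellman observation settings and the noise level.
#' Defaults mirror the transport study the package models: a 15/30/45/60 min
#' reactivation grid, control velocity 1.0, inhibited baseline 0.05
#' (arbitrary absorbance/min units), 5% multiplicative Gaussian velocity
#' noise, and 4 replicates per condition.
#'
#' @param pair [oxime_pair] (or standard-pair name).
#' @param conditions Data frame with columns `carrier`,
#'   `particle_load_mg_cm2`, `loading_dose_uM`, `true_conc_uM` (the hidden
#'   transported basolateral concentration) and optionally `n_replicates`
#'   (otherwise `n_replicates` below applies). See [reference_conditions()].
#' @param scheme [dilution_scheme] used both to dilute truth into the cuvette
#'   and, downstream, to standardize back.
#' @param time_grid Reactivation times, minutes, strictly increasing.
#' @param v_c,v_i True control / inhibited velocities.
#' @param noise_cv Coefficient of variation of the multiplicative Gaussian
#'   measurement noise on every velocity (v_t, v_c, v_i alike); `0` for
#'   noiseless data.
#' @param n_replicates Default replicate count per condition.
#' @param seed Integer root seed; per-replicate substreams are derived
#'   deterministically from it and the condition identity, so adding a
#'   condition never reshuffles existing ones.
#' @return A `simulation_config` object.
#' @examples
#' cfg <- simulation_config(conditions = reference_conditions(1), seed = 1)
#' sim <- simulate_experiment(cfg)
#' names(sim)
#' @export
simulation_config <- function(pair = standard_oxime_pair("obidoxime-paraoxon"),
                              conditions,
                              scheme = dilution_scheme(cuvette_total_ul = 3060),
                              time_grid = c(15, 30, 45, 60),
                              v_c = 1.0, v_i = 0.05,
                              noise_cv = 0.05,
                              n_replicates = 4L,
                              seed = 1L) {
  pair <- as_oxime_pair(pair)
  need <- c("carrier", "particle_load_mg_cm2", "loading_dose_uM", "true_conc_uM")
  if (!is.data.frame(conditions) || !all(need %in% names(conditions))) {
    stop_oxitrans(paste0("`conditions` must contain columns ",
                         paste(need, collapse = ", "), "."), "config")
  }
  if (any(conditions$true_conc_uM < 0)) {
    stop_oxitrans("True concentrations must be non-negative.", "config")
  }
  if (!"n_replicates" %in% names(conditions)) conditions$n_replicates <- as.integer(n_replicates)
  if (any(conditions$n_replicates < 1)) {
    stop_oxitrans("`n_replicates` must be at least 1.", "config")
  }
  if (!is.numeric(noise_cv) || length(noise_cv) != 1 || noise_cv < 0) {
    stop_oxitrans("`noise_cv` must be a single non-negative number.", "config")
  }
  if (any(diff(time_grid) <= 0) || any(time_grid <= 0)) {
    stop_oxitrans("`time_grid` must be positive and strictly increasing.", "config")
  }
  check_velocity_span(v_c, v_i)
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop_oxitrans("`seed` must be a single integer.", "config")
  }
  structure(
    list(pair = pair, conditions = as_tibble(conditions), scheme = scheme,
         time_grid = as.numeric(time_grid), v_c = v_c, v_i = v_i,
         noise_cv = noise_cv, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Default synthetic design mirroring the reference tables
#'
#' Builds a generator design whose hidden true basolateral concentrations are
#' the published standardized concentrations of [transport_reference()], so a
#' noiseless synthetic run reproduces the corresponding table's transport
#' differences.
#'
#' @inheritParams transport_reference
#' @param n_replicates Replicates per condition (default 4).
#' @return Conditions tibble for [simulation_config()].
#' @export
reference_conditions <- function(table_id = 1, n_replicates = 4L) {
  ref <- transport_reference(table_id)
  tibble(
    carrier = ref$carrier,
    particle_load_mg_cm2 = ref$particle_load_mg_cm2,
    loading_dose_uM = ref$loading_dose_uM,
    true_conc_uM = ref$standardized_conc_uM,
    n_replicates = as.integer(n_replicates)
  )
}

# Deterministic 31-bit string hash for per-replicate substreams.
stream_seed <- function(root, id) {
  h <- 0
  for (c in utf8ToInt(id)) h <- (h * 31 + c) %% 2147483647
  as.integer((abs(root) + h) %% 2147483647)
}

#' Simulate a Transwell transport experiment
#'
#' Forward model, per condition and replicate: the hidden basolateral
#' concentration is diluted into the cuvette (divide by the scheme's
#' standardization factor), converted to an observed reactivation rate via the
#' hyperbolic rate law, and expressed as Ellman velocities on the
#' configuration's time grid. Every velocity observation — `v_t` at each time
#' as well as the `v_c`/`v_i` baselines — is perturbed independently by
#' multiplicative Gaussian noise `(1 + e)`, `e ~ N(0, noise_cv)`.
#'
#' Each replicate draws from its own RNG substream derived from the root seed
#' and the condition/replicate identity, so runs are byte-reproducible and
#' extending the design leaves existing rows untouched.
#'
#' @param config A [simulation_config()].
#' @return List of class `transwell_simulation` with tibbles
#'   `timecourses` (`condition_id`, `carrier`, `particle_load_mg_cm2`,
#'   `loading_dose_uM`, `replicate_id`, `t_min`, `v_t`),
#'   `baselines` (`condition_id`, `replicate_id`, `v_c`, `v_i`) and
#'   `truth` (per replicate: true and cuvette concentrations, true rate).
#' @export
simulate_experiment <- function(config) {
  if (!inherits(config, "simulation_config")) {
    stop_oxitrans("`config` must be a simulation_config.", "config")
  }
  factor <- standardization_factor(config$scheme)
  rows <- purrr::pmap(config$conditions, function(carrier, particle_load_mg_cm2,
                                                  loading_dose_uM, true_conc_uM,
                                                  n_replicates, ...) {
    condition_id <- sprintf("%s_%g_%g", carrier, particle_load_mg_cm2, loading_dose_uM)
    cuvette <- true_conc_uM / factor
    k <- kobs_from_conc(cuvette, config$pair)
    purrr::map(seq_len(n_replicates), function(r) {
      replicate_id <- sprintf("r%d", r)
      sseed <- stream_seed(config$seed, paste(condition_id, replicate_id))
      noisy <- local({
        set.seed(sseed)
        n_t <- length(config$time_grid)
        eps <- rnorm(n_t + 2, mean = 0, sd = config$noise_cv)
        v_t <- reactivation_velocity(k, config$time_grid, config$v_c, config$v_i) *
          (1 + eps[seq_len(n_t)])
        list(v_t = v_t,
             v_c = config$v_c * (1 + eps[n_t + 1]),
             v_i = config$v_i * (1 + eps[n_t + 2]))
      })
      list(
        timecourse = tibble(
          condition_id = condition_id, carrier = carrier,
          particle_load_mg_cm2 = particle_load_mg_cm2,
          loading_dose_uM = loading_dose_uM,
          replicate_id = replicate_id,
          t_min = config$time_grid, v_t = noisy$v_t),
        baseline = tibble(
          condition_id = condition_id, replicate_id = replicate_id,
          v_c = noisy$v_c, v_i = noisy$v_i),
        truth = tibble(
          condition_id = condition_id, carrier = carrier,
          particle_load_mg_cm2 = particle_load_mg_cm2,
          loading_dose_uM = loading_dose_uM,
          replicate_id = replicate_id,
          true_conc_uM = true_conc_uM,
          cuvette_conc_uM = cuvette,
          true_kobs = k)
      )
    })
  })
  rows <- purrr::list_flatten(rows)
  structure(
    list(
      timecourses = dplyr::bind_rows(purrr::map(rows, "timecourse")),
      baselines = dplyr::bind_rows(purrr::map(rows, "baseline")),
      truth = dplyr::bind_rows(purrr::map(rows, "truth")),
      config = config
    ),
    class = "transwell_simulation"
  )
}

#' @export
print.transwell_simulation <- function(x, ...) {
  cat(sprintf("<transwell_simulation> %d conditions, %d replicates, %d velocity rows (seed %d)\n",
              nrow(x$config$conditions), nrow(x$baselines), nrow(x$timecourses),
              x$config$seed))
  invisible(x)
}
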