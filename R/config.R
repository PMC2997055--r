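#' Load and validate a run configuration from JSON
#'
#' A run configuration selects the kinetic pair (by standard name, or as
#' explicit constants), the dilution scheme, the reactivation time grid, the
#' reporting convention and statistics options. Unknown keys are rejected
#' rather than ignored, so typos cannot silently fall back to defaults. The
#' resolved configuration is echoed as a message (one line per setting) so
#' every run logs what it actually used.
#'
#' Recognised keys:
#' * `pair`: a standard pair name (`"obidoxime-paraoxon"`, `"hi6-sarin"`), or
#'   an object `{oxime, inhibitor, K_D, k_r}`.
#' * `scheme`: `{cuvette_sample_ul, cuvette_total_ul, apical_ul,
#'   basolateral_ul, transwell_factor}` (`cuvette_total_ul` required).
#' * `time_grid`: array of minutes.
#' * `convention`: `"ratio-of-means"` or `"per-replicate"`.
#' * `reference`: free-drug carrier label.
#' * `noise_cv`, `v_c`, `v_i`, `n_replicates`, `seed`: simulation settings.
#'
#' @param path JSON file path.
#' @param quiet Suppress the resolved-config log lines.
#' @return A named list with elements `pair` ([oxime_pair]), `scheme`
#'   ([dilution_scheme]), `time_grid`, `convention`, `reference`, and any
#'   simulation settings present.
#' @export
read_run_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop_oxitrans(sprintf("Config file not found: %s", path), "config")
  raw <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop_oxitrans(sprintf("Invalid JSON in %s: %s",
                                          basename(path), conditionMessage(e)), "config")
                  })
  known <- c("pair", "scheme", "time_grid", "convention", "reference",
             "noise_cv", "v_c", "v_i", "n_replicates", "seed")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop_oxitrans(sprintf("Unknown config key(s) in %s: %s.",
                          basename(path), paste(unknown, collapse = ", ")), "config")
  }

  pair <- if (is.null(raw$pair)) {
    standard_oxime_pair("obidoxime-paraoxon")
  } else if (is.character(raw$pair)) {
    standard_oxime_pair(raw$pair)
  } else {
    with(raw$pair, oxime_pair(oxime %||% "custom", inhibitor %||% "custom",
                              K_D = K_D, k_r = k_r))
  }

  scheme <- if (is.null(raw$scheme)) NULL else {
    sk <- c("cuvette_sample_ul", "cuvette_total_ul", "apical_ul",
            "basolateral_ul", "transwell_factor")
    unknown_s <- setdiff(names(raw$scheme), sk)
    if (length(unknown_s) > 0) {
      stop_oxitrans(sprintf("Unknown scheme key(s): %s.",
                            paste(unknown_s, collapse = ", ")), "config")
    }
    do.call(dilution_scheme, raw$scheme)
  }

  convention <- raw$convention %||% "ratio-of-means"
  if (!convention %in% c("ratio-of-means", "per-replicate")) {
    stop_oxitrans("`convention` must be 'ratio-of-means' or 'per-replicate'.", "config")
  }

  cfg <- list(
    pair = pair,
    scheme = scheme,
    time_grid = raw$time_grid %||% c(15, 30, 45, 60),
    convention = convention,
    reference = raw$reference %||% "free",
    noise_cv = raw$noise_cv,
    v_c = raw$v_c, v_i = raw$v_i,
    n_replicates = raw$n_replicates,
    seed = raw$seed
  )
  if (!quiet) {
    message(sprintf("config: pair = %s/%s (K_D = %g uM, k_r = %g min^-1)",
                    pair$oxime, pair$inhibitor, pair$K_D, pair$k_r))
    if (!is.null(scheme)) {
      message(sprintf("config: scheme = %g ul in %g ul (factor %.4g)",
                      scheme$cuvette_sample_ul, scheme$cuvette_total_ul,
                      standardization_factor(scheme)))
    }
    message(sprintf("config: time grid = {%s} min; convention = %s",
                    paste(cfg$time_grid, collapse = ", "), convention))
    if (!is.null(cfg$seed)) message(sprintf("config: seed = %d", as.integer(cfg$seed)))
  }
  cfg
}
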