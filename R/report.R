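#' Assemble the transport report
#'
#' Groups transport records by particle load × loading dose and, within each
#' group, reports every carrier's mean standardized concentration together
#' with its transport difference versus the free-oxime reference, under both
#' conventions:
#'
#' * `diff_ratio_means_pct` — ratio of group means,
#'   `100 * (mean(c_test) / mean(c_free) - 1)`; the default convention.
#' * `diff_per_replicate_pct` — mean over replicate-matched pairs of
#'   `100 * (c_test_i - c_free_i) / c_free_i`; `NA` when replicate IDs do not
#'   pair up across carriers.
#'
#' The two agree for single-replicate groups and diverge for replicated ones;
#' both are always emitted so neither can be mistaken for the other. Censored
#' records are excluded from means with a warning. Row order is fixed:
#' particle load descending, loading dose ascending (0.52/100, 0.52/1000,
#' 0.26/100, 0.26/1000 for the standard design), carriers within a group in
#' first-appearance order with the reference last.
#'
#' @param records Tibble of transport records (see [quantify_transport()] or
#'   [transport_reference()]): columns `carrier`, `particle_load_mg_cm2`,
#'   `loading_dose_uM`, `standardized_conc_uM`, optionally `replicate_id`
#'   and `censored`.
#' @param reference Carrier label of the free-drug control. Default `"free"`.
#' @param convention Which difference fills the `transport_difference_pct`
#'   column: `"ratio-of-means"` (default) or `"per-replicate"`. Both source
#'   columns are always present.
#' @return A `transport_report` tibble: one row per group × carrier with
#'   `n`, `mean_standardized_uM`, `sd_standardized_uM`, the two difference
#'   columns, and `transport_difference_pct` per `convention` (`NA` for the
#'   reference rows).
#' @examples
#' transport_report(transport_reference(1))
#' @export
transport_report <- function(records, reference = "free",
                             convention = c("ratio-of-means", "per-replicate")) {
  convention <- match.arg(convention)
  need <- c("carrier", "particle_load_mg_cm2", "loading_dose_uM", "standardized_conc_uM")
  if (!is.data.frame(records) || !all(need %in% names(records))) {
    stop_oxitrans(paste0("`records` must contain columns ", paste(need, collapse = ", "), "."),
                  "report")
  }
  records <- as_tibble(records)
  if (!"replicate_id" %in% names(records)) records$replicate_id <- "r1"
  if ("censored" %in% names(records) && any(records$censored, na.rm = TRUE)) {
    warn(sprintf("%d censored record(s) excluded from group means.",
                 sum(records$censored, na.rm = TRUE)))
    records <- records[!records$censored %in% TRUE, ]
  }

  groups <- records |>
    dplyr::distinct(.data$particle_load_mg_cm2, .data$loading_dose_uM) |>
    dplyr::arrange(dplyr::desc(.data$particle_load_mg_cm2), .data$loading_dose_uM)

  missing_ref <- groups |>
    dplyr::anti_join(
      dplyr::filter(records, .data$carrier == reference),
      by = c("particle_load_mg_cm2", "loading_dose_uM"))
  if (nrow(missing_ref) > 0) {
    stop_oxitrans(paste0(
      "No free-oxime reference ('", reference, "') in group(s): ",
      paste(sprintf("%g mg/cm2 x %g uM", missing_ref$particle_load_mg_cm2,
                    missing_ref$loading_dose_uM), collapse = "; ")),
      "report")
  }

  carrier_order <- unique(records$carrier)
  carrier_order <- c(setdiff(carrier_order, reference), reference)

  out <- purrr::pmap(groups, function(particle_load_mg_cm2, loading_dose_uM) {
    grp <- dplyr::filter(records,
                         .data$particle_load_mg_cm2 == !!particle_load_mg_cm2,
                         .data$loading_dose_uM == !!loading_dose_uM)
    ref <- dplyr::filter(grp, .data$carrier == reference)
    ref_mean <- mean(ref$standardized_conc_uM)
    purrr::map(intersect(carrier_order, unique(grp$carrier)), function(ca) {
      g <- dplyr::filter(grp, .data$carrier == ca)
      is_ref <- identical(ca, reference)
      m <- mean(g$standardized_conc_uM)
      drm <- if (is_ref) NA_real_ else transport_difference(m, ref_mean)
      dpr <- if (is_ref) NA_real_ else {
        paired <- dplyr::inner_join(
          g[, c("replicate_id", "standardized_conc_uM")],
          ref[, c("replicate_id", "standardized_conc_uM")],
          by = "replicate_id", suffix = c("_test", "_free"))
        if (nrow(paired) == 0) NA_real_ else
          mean(transport_difference(paired$standardized_conc_uM_test,
                                    paired$standardized_conc_uM_free))
      }
      tibble(
        particle_load_mg_cm2 = particle_load_mg_cm2,
        loading_dose_uM = loading_dose_uM,
        carrier = ca,
        n = nrow(g),
        mean_standardized_uM = m,
        sd_standardized_uM = if (nrow(g) > 1) stats::sd(g$standardized_conc_uM) else NA_real_,
        diff_ratio_means_pct = drm,
        diff_per_replicate_pct = dpr
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  out$transport_difference_pct <- if (convention == "ratio-of-means") {
    out$diff_ratio_means_pct
  } else {
    out$diff_per_replicate_pct
  }
  attr(out, "convention") <- convention
  attr(out, "reference") <- reference
  class(out) <- c("transport_report", class(out))
  out
}

#' Compare two carriers with the exact Mann-Whitney U test
#'
#' Convenience wrapper running [mann_whitney_exact()] on the standardized
#' concentrations of two carriers, optionally within one particle-load ×
#' loading-dose group, pooling replicates.
#'
#' @inheritParams transport_report
#' @param carrier_a,carrier_b Carrier labels to compare.
#' @param particle_load_mg_cm2,loading_dose_uM Optional filters restricting
#'   the comparison to one design cell.
#' @param ... Passed to [mann_whitney_exact()].
#' @return A one-row tibble (see [tidy()] of `mw_test`) with the group
#'   filters attached.
#' @export
compare_transport <- function(records, carrier_a, carrier_b,
                              particle_load_mg_cm2 = NULL, loading_dose_uM = NULL,
                              ...) {
  sel <- records
  if (!is.null(particle_load_mg_cm2)) {
    sel <- dplyr::filter(sel, .data$particle_load_mg_cm2 == !!particle_load_mg_cm2)
  }
  if (!is.null(loading_dose_uM)) {
    sel <- dplyr::filter(sel, .data$loading_dose_uM == !!loading_dose_uM)
  }
  a <- sel$standardized_conc_uM[sel$carrier == carrier_a]
  b <- sel$standardized_conc_uM[sel$carrier == carrier_b]
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0) {
    stop_oxitrans("Both carriers need at least one uncensored record to compare.", "domain")
  }
  res <- mann_whitney_exact(a, b, label_a = carrier_a, label_b = carrier_b, ...)
  out <- tidy(res)
  out$particle_load_mg_cm2 <- particle_load_mg_cm2 %||% NA_real_
  out$loading_dose_uM <- loading_dose_uM %||% NA_real_
  out
}

#' @exportS3Method ggplot2::autoplot
autoplot.transport_report <- function(object, ...) {
  df <- as_tibble(object)
  df$group <- sprintf("%g mg/cm², %g µM",
                      df$particle_load_mg_cm2, df$loading_dose_uM)
  df$group <- factor(df$group, levels = unique(df$group))
  df$carrier <- factor(df$carrier, levels = unique(df$carrier))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$carrier, y = .data$mean_standardized_uM,
                                   fill = .data$carrier)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~group, nrow = 1) +
    ggplot2::labs(x = NULL, y = "standardized [oxime] (µM)") +
    ggplot2::guides(fill = "none")
}
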