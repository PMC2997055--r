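#' Read Ellman time courses and baselines from CSV
#'
#' The time-course dialect has one row per velocity measurement with header
#' `condition_id, carrier, particle_load_mg_cm2, loading_dose_uM,
#' replicate_id, t_min, v_t` (metadata columns optional); the companion
#' baseline file has `condition_id, replicate_id, v_c, v_i`. UTF-8, decimal
#' point, RFC-4180 quoting. Validation errors name the file, line and field;
#' line numbers count the header as line 1.
#'
#' @param path Time-course CSV path.
#' @param baselines_path Companion baseline CSV path.
#' @return List with tibbles `timecourses` and `baselines`, ready for
#'   [quantify_transport()].
#' @export
read_timecourses <- function(path, baselines_path) {
  tc <- read_checked_csv(path,
    required = c("condition_id", "replicate_id", "t_min", "v_t"),
    numeric_cols = c("t_min", "v_t", "particle_load_mg_cm2", "loading_dose_uM"))
  bl <- read_checked_csv(baselines_path,
    required = c("condition_id", "v_c", "v_i"),
    numeric_cols = c("v_c", "v_i"))
  # linkage: every time course needs a baseline row
  keys <- intersect(c("condition_id", "replicate_id"), names(bl))
  orphan <- dplyr::anti_join(dplyr::distinct(tc[, keys]), bl[, keys], by = keys)
  if (nrow(orphan) > 0) {
    stop_oxitrans(sprintf(
      "%s: missing v_c/v_i companion entry for condition '%s'%s.",
      basename(baselines_path), orphan$condition_id[1],
      if ("replicate_id" %in% keys) sprintf(" replicate '%s'", orphan$replicate_id[1]) else ""),
      "io")
  }
  list(timecourses = tc, baselines = bl)
}

read_checked_csv <- function(path, required, numeric_cols) {
  if (!file.exists(path)) stop_oxitrans(sprintf("File not found: %s", path), "io")
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop_oxitrans(sprintf("%s: missing required column(s): %s.",
                          basename(path), paste(missing, collapse = ", ")), "io")
  }
  for (col in intersect(numeric_cols, names(raw))) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(vals) & !is.na(raw[[col]]))
    if (length(bad) > 0) {
      stop_oxitrans(sprintf("%s: line %d: field `%s` is not numeric (got '%s').",
                            basename(path), bad[1] + 1L, col, raw[[col]][bad[1]]), "io")
    }
    na <- which(is.na(raw[[col]]))
    if (length(na) > 0) {
      stop_oxitrans(sprintf("%s: line %d: field `%s` is missing.",
                            basename(path), na[1] + 1L, col), "io")
    }
    raw[[col]] <- vals
  }
  raw
}

#' Write a simulated experiment to CSV
#'
#' Emits `timecourses.csv`, `baselines.csv` and `truth.csv` in the dialect
#' [read_timecourses()] consumes. Output is deterministic: identical
#' simulations produce byte-identical files.
#'
#' @param sim A `transwell_simulation` (from [simulate_experiment()]).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_timecourses <- function(sim, dir) {
  if (!inherits(sim, "transwell_simulation")) {
    stop_oxitrans("`sim` must be a transwell_simulation.", "io")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("timecourses.csv", "baselines.csv", "truth.csv"))
  readr::write_csv(sim$timecourses, paths[1])
  readr::write_csv(sim$baselines, paths[2])
  readr::write_csv(sim$truth, paths[3])
  invisible(paths)
}

#' Write transport records to CSV
#'
#' @param records Tibble of transport records.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_transport_records <- function(records, path) {
  readr::write_csv(records, path)
  invisible(path)
}

#' Render a transport report as Markdown
#'
#' Mirrors the layout of the study's result tables: one row per particle-load
#' × loading-dose group; per carrier, the standardized concentration (2
#' decimal places) and, for non-reference carriers, the transport difference
#' (2 decimal places, explicit sign). An optional statistics section lists
#' group comparisons; it is omitted when `comparisons` is empty or `NULL`.
#' Output is deterministic: identical inputs give byte-identical files.
#'
#' @param report A `transport_report` (from [transport_report()]).
#' @param path Output file path; `NULL` returns the text invisibly without
#'   writing.
#' @param comparisons Optional tibble of comparisons (see
#'   [compare_transport()]).
#' @param title Report heading.
#' @return Invisibly, the report text (one string per line).
#' @export
write_transport_report <- function(report, path = NULL, comparisons = NULL,
                                   title = "Transport study report") {
  if (!inherits(report, "transport_report")) {
    stop_oxitrans("`report` must come from transport_report().", "io")
  }
  ref <- attr(report, "reference")
  carriers <- setdiff(unique(report$carrier), ref)
  groups <- dplyr::distinct(report, .data$particle_load_mg_cm2, .data$loading_dose_uM)

  fmt_conc <- function(x) sprintf("%.2f", x)
  fmt_diff <- function(x) sprintf("%+.2f", x)

  header <- c("[NP], [drug-loading]",
              unlist(purrr::map(carriers, ~ c(paste0(.x, " standardized [oxime](uM)"),
                                              paste0(.x, " transport difference(%)")))),
              paste0(ref, " standardized [oxime](uM)"))
  rows <- purrr::pmap_chr(groups, function(particle_load_mg_cm2, loading_dose_uM) {
    grp <- dplyr::filter(report,
                         .data$particle_load_mg_cm2 == !!particle_load_mg_cm2,
                         .data$loading_dose_uM == !!loading_dose_uM)
    cells <- unlist(purrr::map(carriers, function(ca) {
      g <- grp[grp$carrier == ca, ]
      if (nrow(g) == 0) return(c("-", "-"))
      c(fmt_conc(g$mean_standardized_uM), fmt_diff(g$transport_difference_pct))
    }))
    refcell <- fmt_conc(grp$mean_standardized_uM[grp$carrier == ref])
    paste(c(sprintf("%g mg NP/cm2, %g uM", particle_load_mg_cm2, loading_dose_uM),
            cells, refcell), collapse = " | ")
  })

  lines <- c(
    paste0("# ", title),
    "",
    sprintf("Difference convention: %s.", attr(report, "convention")),
    "",
    paste(header, collapse = " | "),
    paste(rep("---", length(header)), collapse = " | "),
    rows
  )

  if (!is.null(comparisons) && nrow(comparisons) > 0) {
    stat_rows <- purrr::pmap_chr(
      comparisons[, c("group_a", "group_b", "u_statistic", "p_value", "approximate")],
      function(group_a, group_b, u_statistic, p_value, approximate) {
        sprintf("- %s vs %s: U = %g, two-tailed p = %.4f%s%s",
                group_a, group_b, u_statistic, p_value,
                if (p_value < 0.05) " (significant at P<0.05)" else "",
                if (approximate) " [approximate]" else "")
      })
    lines <- c(lines, "", "## Statistics (two-tailed Mann-Whitney U)", "", stat_rows)
  }

  if (!is.null(path)) {
    con <- file(path, open = "wb")  # fixed newlines for byte-identical output
    on.exit(close(con))
    writeLines(lines, con, sep = "\n", useBytes = TRUE)
  }
  invisible(lines)
}
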