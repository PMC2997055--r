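#' Dilution scheme of the transport assay
#'
#' Describes how the collected basolateral medium is diluted on its way into
#' the Ellman cuvette, so that the concentration inferred from the
#' reactivation rate (the *cuvette* concentration) can be standardized back to
#' the transported concentration. The sample aliquot defaults to 750 µl of
#' collected medium; the total cuvette volume (sample + buffer + DTNB +
#' enzyme + substrate) has no default and must be stated for any given assay.
#'
#' The Transwell leg of standardization — accounting for apical/basolateral
#' compartment volumes when converting a concentration into an amount or onto
#' another compartment's scale — is a separate multiplicative `transwell_factor`
#' that defaults to 1 (report the basolateral concentration as-is).
#'
#' @param cuvette_sample_ul Volume of collected medium pipetted into the
#'   cuvette, µl. Default 750.
#' @param cuvette_total_ul Total cuvette volume, µl; must be `>=`
#'   `cuvette_sample_ul`. No default.
#' @param apical_ul,basolateral_ul Optional Transwell compartment volumes, µl
#'   (metadata; not used unless folded into `transwell_factor`).
#' @param transwell_factor Extra multiplicative standardization factor for the
#'   Transwell system; default 1.
#' @return An object of class `dilution_scheme`.
#' @examples
#' scheme <- dilution_scheme(cuvette_total_ul = 3060)
#' standardization_factor(scheme)  # 3060 / 750 = 4.08
#' @export
dilution_scheme <- function(cuvette_sample_ul = 750, cuvette_total_ul,
                            apical_ul = NULL, basolateral_ul = NULL,
                            transwell_factor = 1) {
  if (missing(cuvette_total_ul)) {
    stop_oxitrans("`cuvette_total_ul` must be supplied; there is no default cuvette volume.",
                  "config")
  }
  for (v in list(cuvette_sample_ul = cuvette_sample_ul,
                 cuvette_total_ul = cuvette_total_ul,
                 transwell_factor = transwell_factor)) {
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0) {
      stop_oxitrans("Dilution-scheme volumes and factors must be single positive numbers.",
                    "config")
    }
  }
  if (cuvette_total_ul < cuvette_sample_ul) {
    stop_oxitrans("`cuvette_total_ul` must be at least `cuvette_sample_ul`.", "config")
  }
  structure(
    list(cuvette_sample_ul = cuvette_sample_ul,
         cuvette_total_ul = cuvette_total_ul,
         apical_ul = apical_ul, basolateral_ul = basolateral_ul,
         transwell_factor = transwell_factor),
    class = "dilution_scheme"
  )
}

#' @rdname dilution_scheme
#' @param scheme A `dilution_scheme`.
#' @export
standardization_factor <- function(scheme) {
  if (!inherits(scheme, "dilution_scheme")) {
    stop_oxitrans("`scheme` must be a dilution_scheme.", "config")
  }
  scheme$cuvette_total_ul / scheme$cuvette_sample_ul * scheme$transwell_factor
}

#' @export
print.dilution_scheme <- function(x, ...) {
  cat(sprintf("<dilution_scheme> %g ul sample in %g ul cuvette (factor %.4g)",
              x$cuvette_sample_ul, x$cuvette_total_ul, standardization_factor(x)))
  if (x$transwell_factor != 1) cat(sprintf(", transwell factor %g", x$transwell_factor))
  cat("\n")
  invisible(x)
}

#' Standardize a cuvette concentration for dilution
#'
#' Multiplies the oxime concentration measured in the assay cuvette by the
#' scheme's standardization factor (cuvette total / sample volume, times any
#' Transwell factor), recovering the concentration in the collected medium.
#' Linear by construction: `standardize_concentration(a * c) = a *
#' standardize_concentration(c)`.
#'
#' @param cuvette_conc Concentration in the cuvette, µM, non-negative
#'   (vectorised).
#' @inheritParams standardization_factor
#' @return Standardized concentration, µM.
#' @examples
#' standardize_concentration(1.2, dilution_scheme(750, 3000))  # 4.8
#' @export
standardize_concentration <- function(cuvette_conc, scheme) {
  check_number(cuvette_conc, "cuvette_conc", lower = 0)
  cuvette_conc * standardization_factor(scheme)
}

#' Transport difference relative to the free drug
#'
#' Percent change of the transported (standardized) oxime concentration for a
#' carrier formulation relative to the free-oxime control:
#' \eqn{100 (c_{test} - c_{free}) / c_{free}}. Signs are always carried: a
#' formulation transporting less than the free drug yields a negative
#' difference.
#'
#' @param c_test Standardized concentration for the test formulation, µM,
#'   non-negative (vectorised).
#' @param c_free Standardized concentration for the free-drug reference, µM,
#'   strictly positive.
#' @return Transport difference in percent.
#' @examples
#' transport_difference(15.06, 10.83)  # +39.06 %
#' @export
transport_difference <- function(c_test, c_free) {
  check_number(c_test, "c_test", lower = 0)
  if (!is.numeric(c_free) || anyNA(c_free) || any(c_free <= 0)) {
    stop_oxitrans("`c_free` must be strictly positive: the free-drug reference defines the scale.",
                  "undefined_reference")
  }
  100 * (c_test - c_free) / c_free
}
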