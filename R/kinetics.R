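#' Pseudo-first-order reactivation rate law
#'
#' Reactivation of organophosphate-inhibited AChE by an oxime proceeds through
#' a reversible phosphyl-enzyme-oxime complex followed by displacement of the
#' phosphyl residue. With the oxime in large excess over inhibited enzyme the
#' kinetics reduce to a pseudo-first-order process whose observed rate
#' saturates hyperbolically in the oxime concentration:
#'
#' \deqn{k_{obs} = \frac{k_r \, [Ox]}{K_D + [Ox]}}
#'
#' `kobs_from_conc()` evaluates this forward rate law;
#' `conc_from_kobs()` is its exact algebraic inverse,
#' \eqn{[Ox] = K_D \, k_{obs} / (k_r - k_{obs})}, which turns a fitted rate
#' into the oxime concentration present in the assay cuvette — the biosensor
#' readout at the heart of the pipeline.
#'
#' @param conc Oxime concentration, µM; non-negative, vectorised.
#' @param kobs Observed reactivation rate, min^-1; must satisfy
#'   `0 <= kobs < k_r` for inversion. A rate at or above `k_r` means the
#'   hyperbola has saturated and no finite concentration is identifiable:
#'   `conc_from_kobs()` then throws an `oxitrans_saturation_error`.
#' @param pair An [oxime_pair] (or the name of a standard pair).
#'
#' @return Numeric vector: rates in min^-1 (`kobs_from_conc`) or
#'   concentrations in µM (`conc_from_kobs`).
#' @examples
#' obi <- standard_oxime_pair("obidoxime-paraoxon")
#' kobs_from_conc(32.20, obi)      # half-maximal rate k_r / 2 = 0.405
#' conc_from_kobs(0.405, obi)      # recovers K_D = 32.20
#' @export
kobs_from_conc <- function(conc, pair) {
  pair <- as_oxime_pair(pair)
  check_number(conc, "conc", lower = 0)
  pair$k_r * conc / (pair$K_D + conc)
}

#' @rdname kobs_from_conc
#' @export
conc_from_kobs <- function(kobs, pair) {
  pair <- as_oxime_pair(pair)
  check_number(kobs, "kobs", lower = 0)
  if (any(kobs >= pair$k_r)) {
    stop_oxitrans(
      sprintf(paste0(
        "Unresolvable concentration: k_obs (%g min^-1) is at or above the rate ",
        "ceiling k_r = %g min^-1; the rate law has saturated."),
        max(kobs), pair$k_r),
      "saturation")
  }
  pair$K_D * kobs / (pair$k_r - kobs)
}

#' Predicted reactivation time course
#'
#' With maximal reactivation defined as 100%, the reactivated fraction follows
#' a monoexponential recovery \eqn{1 - e^{-k_{obs} t}}.
#' `reactivation_velocity()` maps that fraction onto the measured Ellman-assay
#' velocity scale, interpolating between the inhibited baseline `v_i` (no
#' reactivation) and the control velocity `v_c` (full activity):
#' \eqn{v(t) = v_i + (v_c - v_i)\,(1 - e^{-k_{obs} t})}.
#'
#' @param kobs Observed rate, min^-1, non-negative.
#' @param t Reactivation time, minutes, non-negative. `kobs` and `t` recycle
#'   against each other.
#' @param v_c Control (maximal) velocity; arbitrary but consistent units.
#' @param v_i Velocity of the inhibited enzyme, same units; requires
#'   `v_c > v_i >= 0`.
#' @return Reactivated fraction in `[0, 1)`, or predicted velocity.
#' @examples
#' reactivation_fraction(log(2) / 15, 15)   # one half-life -> 0.5
#' reactivation_velocity(log(2) / 15, 15, v_c = 1, v_i = 0.2)
#' @export
reactivation_fraction <- function(kobs, t) {
  check_number(kobs, "kobs", lower = 0)
  check_number(t, "t", lower = 0)
  1 - exp(-kobs * t)
}

#' @rdname reactivation_fraction
#' @export
reactivation_velocity <- function(kobs, t, v_c, v_i) {
  check_velocity_span(v_c, v_i)
  v_i + (v_c - v_i) * reactivation_fraction(kobs, t)
}

check_velocity_span <- function(v_c, v_i) {
  check_number(v_c, "v_c", lower = 0)
  check_number(v_i, "v_i", lower = 0)
  if (any(v_c <= v_i)) {
    stop_oxitrans(
      "Degenerate assay: control velocity v_c must exceed inhibited velocity v_i.",
      "degenerate_assay")
  }
  invisible(TRUE)
}

#' Fit the observed reactivation rate to an activity time course
#'
#' Nonlinear least squares in the single parameter `k_obs`: the residual sum
#' of squares between measured velocities and
#' [reactivation_velocity()] is minimised over a bounded interval
#' `[0, 10 k_r]`. The plateau is fixed by the measured `v_c` and `v_i`
#' (matching how the assay is run: both baselines are measured, not fitted);
#' set `fit_plateau = TRUE` to co-fit the span as an explicit option.
#'
#' The search is a dense-grid bracketing pass followed by golden-section /
#' parabolic refinement, which is robust for this one-dimensional, smooth
#' objective. A solution in the top 0.1% of the search interval — or one whose
#' objective the interval's upper bound matches, which happens when every
#' exponential has saturated and the likelihood is flat in `k_obs` — sets
#' `censored_high`: the time course is consistent with arbitrarily fast
#' reactivation and no finite rate (hence no concentration) is identifiable.
#' Apparent fractions below zero (noise pushing `v_t` under `v_i`) are fitted
#' as-is — clipping them would bias `k_obs` upward — and flagged via
#' `negative_fractions`.
#'
#' @param data Data frame with one row per measurement; columns `t` (minutes,
#'   strictly increasing, positive) and `v_t` (velocity). At least two rows.
#' @param pair [oxime_pair] supplying the bound `10 k_r` for the search.
#' @param v_c,v_i Measured control and inhibited-baseline velocities.
#' @param fit_plateau If `TRUE`, co-fit the span `v_c - v_i` together with
#'   `k_obs` (profiled linearly); the baselines remain the anchor for the
#'   reported fraction scale.
#' @param condition_id Optional label carried into errors and printouts.
#'
#' @return A `reactivation_fit` object with elements `kobs` (min^-1),
#'   `residual_sum_squares`, `n_points`, `converged`, `censored_high`,
#'   `negative_fractions`, plus the inputs. [generics::tidy()] and
#'   [generics::glance()] methods return tibbles; `autoplot()` draws the
#'   fitted recovery curve over the data.
#' @examples
#' obi <- standard_oxime_pair("obidoxime-paraoxon")
#' tc <- tibble::tibble(t = c(15, 30, 45, 60),
#'                      v_t = reactivation_velocity(0.05, c(15, 30, 45, 60), 1, 0.1))
#' fit_kobs(tc, obi, v_c = 1, v_i = 0.1)
#' @export
fit_kobs <- function(data, pair, v_c, v_i, fit_plateau = FALSE, condition_id = NULL) {
  pair <- as_oxime_pair(pair)
  if (!is.data.frame(data) || !all(c("t", "v_t") %in% names(data))) {
    stop_oxitrans("`data` must be a data frame with columns `t` and `v_t`.", "domain")
  }
  t <- as.numeric(data$t)
  v_t <- as.numeric(data$v_t)
  if (length(t) < 2) {
    stop_oxitrans("At least two time points are required to fit k_obs.", "domain")
  }
  if (anyNA(t) || anyNA(v_t)) stop_oxitrans("`t` and `v_t` must be non-missing.", "domain")
  if (any(t <= 0)) stop_oxitrans("Reactivation times must be positive.", "domain")
  if (is.unsorted(t, strictly = TRUE)) {
    stop_oxitrans("Reactivation times must be strictly increasing.", "domain")
  }
  check_velocity_span(v_c, v_i)

  upper <- 10 * pair$k_r
  span <- v_c - v_i
  ssr <- if (fit_plateau) {
    function(k) {
      f <- 1 - exp(-k * t)
      # profile the span: best linear amplitude given k (kept non-negative)
      a <- if (sum(f^2) > 0) max(0, sum(f * (v_t - v_i)) / sum(f^2)) else 0
      sum((v_t - v_i - a * f)^2)
    }
  } else {
    function(k) sum((v_t - v_i - span * (1 - exp(-k * t)))^2)
  }

  # dense bracketing grid, then local refinement of the best bracket
  grid <- seq(0, upper, length.out = 1024L)
  vals <- vapply(grid, ssr, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- optimize(ssr, lower = lo, upper = hi, tol = 1e-12)
  kobs <- opt$minimum
  rss <- opt$objective
  # snap to the boundary when it is the true minimiser
  if (ssr(0) <= rss) {
    kobs <- 0
    rss <- ssr(0)
  }
  # censored when the bound fits as well as the minimum: the objective can
  # plateau (saturated exponentials) well before k reaches the bound itself
  at_ceiling <- kobs > 0 &&
    (kobs >= 0.999 * upper ||
       ssr(upper) <= rss + 1e-13 * max(ssr(0), .Machine$double.xmin))

  structure(
    list(
      kobs = kobs,
      residual_sum_squares = rss,
      n_points = length(t),
      converged = TRUE,
      censored_high = at_ceiling,
      negative_fractions = any(v_t < v_i),
      t = t, v_t = v_t, v_c = v_c, v_i = v_i,
      fit_plateau = fit_plateau,
      pair = pair,
      condition_id = condition_id
    ),
    class = "reactivation_fit"
  )
}

#' @export
print.reactivation_fit <- function(x, ...) {
  id <- if (is.null(x$condition_id)) "" else paste0(" [", x$condition_id, "]")
  cat(sprintf("<reactivation_fit>%s k_obs = %.6g min^-1 (RSS = %.3g, n = %d)\n",
              id, x$kobs, x$residual_sum_squares, x$n_points))
  if (x$censored_high) cat("  censored: rate at search ceiling; concentration unidentifiable\n")
  if (x$negative_fractions) cat("  note: some v_t below v_i (negative apparent fractions)\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.reactivation_fit <- function(x, ...) {
  tibble(term = "k_obs", estimate = x$kobs, unit = "1/min")
}

#' @exportS3Method generics::glance
glance.reactivation_fit <- function(x, ...) {
  tibble(
    kobs = x$kobs,
    residual_sum_squares = x$residual_sum_squares,
    n_points = x$n_points,
    converged = x$converged,
    censored_high = x$censored_high,
    negative_fractions = x$negative_fractions
  )
}

#' @export
predict.reactivation_fit <- function(object, t = NULL, ...) {
  t <- t %||% object$t
  reactivation_velocity(object$kobs, t, object$v_c, object$v_i)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @exportS3Method ggplot2::autoplot
autoplot.reactivation_fit <- function(object, ...) {
  obs <- tibble(t = object$t, v_t = object$v_t)
  tt <- seq(0, max(object$t), length.out = 200)
  fit <- tibble(t = tt, v_t = predict(object, tt))
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$t, y = .data$v_t)) +
    ggplot2::geom_line(data = fit, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(object$v_i, object$v_c), linetype = "dotted") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "reactivation time (min)", y = "Ellman velocity",
      title = sprintf("k_obs = %.4g min^-1%s", object$kobs,
                      if (object$censored_high) " (censored)" else "")
    )
}
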