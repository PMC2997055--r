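#' Oxime/inhibitor kinetic constant pairs
#'
#' A reactivation experiment is parameterised by the oxime-enzyme pairing:
#' `K_D`, the dissociation constant of the phosphyl-AChE-oxime complex
#' (inversely proportional to the oxime's affinity for the inhibited enzyme),
#' and `k_r`, the rate constant for displacement of the phosphyl residue
#' (the oxime's reactivity). Both are treated as known inputs, determined
#' independently for each oxime/organophosphate combination; they are never
#' estimated from transport data.
#'
#' `oxime_pair()` builds a pairing from explicit constants.
#' `standard_oxime_pair()` returns one of the two built-in pairings used by
#' the enzymatic biosensor assay this package models:
#'
#' * `"obidoxime-paraoxon"`: obidoxime dichloride reactivating
#'   paraoxon-ethyl-inhibited AChE, `K_D = 32.20` µM, `k_r = 0.81` min^-1.
#' * `"hi6-sarin"`: HI 6 salts reactivating sarin-inhibited AChE,
#'   `K_D = 50.10` µM, `k_r = 0.677` min^-1.
#'
#' @param oxime,inhibitor Text labels for the reactivator and the
#'   organophosphate inhibitor.
#' @param K_D Dissociation constant, µM; must be positive.
#' @param k_r Reactivity rate constant, min^-1; must be positive.
#' @param name One of `"obidoxime-paraoxon"`, `"hi6-sarin"`.
#'
#' @return An object of class `oxime_pair`: a list with elements `oxime`,
#'   `inhibitor`, `K_D`, `k_r`.
#' @examples
#' standard_oxime_pair("obidoxime-paraoxon")
#' oxime_pair("HLo 7", "tabun", K_D = 120, k_r = 0.2)
#' @export
oxime_pair <- function(oxime, inhibitor, K_D, k_r) {
  check_number(K_D, "K_D", lower = 0, allow_zero = FALSE)
  check_number(k_r, "k_r", lower = 0, allow_zero = FALSE)
  structure(
    list(oxime = as.character(oxime), inhibitor = as.character(inhibitor),
         K_D = as.numeric(K_D), k_r = as.numeric(k_r)),
    class = "oxime_pair"
  )
}

#' @rdname oxime_pair
#' @export
standard_oxime_pair <- function(name = c("obidoxime-paraoxon", "hi6-sarin")) {
  name <- match.arg(name)
  switch(name,
    "obidoxime-paraoxon" = oxime_pair("obidoxime", "paraoxon-ethyl", K_D = 32.20, k_r = 0.81),
    "hi6-sarin"          = oxime_pair("HI 6", "sarin", K_D = 50.10, k_r = 0.677)
  )
}

#' @export
print.oxime_pair <- function(x, ...) {
  cat(sprintf("<oxime_pair> %s / %s: K_D = %g uM, k_r = %g min^-1\n",
              x$oxime, x$inhibitor, x$K_D, x$k_r))
  invisible(x)
}

as_oxime_pair <- function(pair) {
  if (inherits(pair, "oxime_pair")) return(pair)
  if (is.character(pair) && length(pair) == 1) return(standard_oxime_pair(pair))
  stop_oxitrans("`pair` must be an oxime_pair or the name of a standard pair.", "config")
}
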