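# Small numeric helpers shared across modules.

#' Clamp probabilities away from the boundary
#'
#' @param p numeric vector of probabilities.
#' @param eps half-width of the exclusion zone at each boundary.
#' @return `p` with values forced into `[eps, 1 - eps]`.
#' @keywords internal
clamp_prob <- function(p, eps = 1e-6) {
  pmin(pmax(p, eps), 1 - eps)
}

#' @keywords internal
logit <- function(p) stats::qlogis(p)

#' @keywords internal
inv_logit <- function(x) stats::plogis(x)

# Canonical MIKE region labels (continent = union of the four).
#' The four MIKE regions
#'
#' Character vector of the region labels recognised throughout the package.
#' @export
mike_regions <- function() c("Central", "Eastern", "Southern", "West")
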