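# The carcass-weighted least-squares-means PIKE model used by the MIKE
# program: a general linear model of raw PIKE (K/C) on region and year fixed
# effects with observations weighted by total carcasses reported. Kept here
# as the comparison baseline; its known failure modes (identical output under
# a ten-fold increase in all counts, truncated confidence intervals, missing
# years appearing as undefined estimates) are what the state-space model
# addresses.

#' Fit the least-squares-means PIKE baseline
#'
#' Weighted linear model `K/C ~ effect + year` (both as factors) with weights
#' equal to total carcasses `C`. The year least-squares mean is the year
#' effect plus the unweighted average of the effect-level estimates, i.e. the
#' model-adjusted marginal mean at each year. Confidence intervals are
#' normal-theory, truncated to `[0, 1]`. Years with no observations are
#' reported as `NA`.
#'
#' @param records data frame with columns `site_id, region, year,
#'   total_carcasses, illegal_carcasses` (only rows with `C >= 1` are used),
#'   e.g. from [write_carcass_table()].
#' @param years years at which to report LS means; default all years present.
#' @param effect `"region"` (as the continental model is printed) or
#'   `"site"`.
#' @param conf confidence level.
#' @return an object of class `ls_means_result`: data frame with `year,
#'   pike_lsmean, se, ci_lo, ci_hi`; the fitted `lm` and simple residual
#'   diagnostics (Shapiro-Wilk normality P, lag-1 residual autocorrelation)
#'   are attached as attributes.
#' @export
fit_ls_means <- function(records, years = NULL,
                         effect = c("region", "site"), conf = 0.95) {
  effect <- match.arg(effect)
  d <- records[records$total_carcasses >= 1, , drop = FALSE]
  if (nrow(d) == 0L) stop("no usable observations (need C >= 1)")
  d$pike <- d$illegal_carcasses / d$total_carcasses
  d$eff <- factor(if (effect == "region") d$region else d$site_id)
  d$fyear <- factor(d$year)
  if (nlevels(d$fyear) < 2L) stop("need >= 2 years with data")
  fit <- if (nlevels(d$eff) > 1L) {
    stats::lm(pike ~ eff + fyear, data = d, weights = total_carcasses)
  } else {
    stats::lm(pike ~ fyear, data = d, weights = total_carcasses)
  }
  if (is.null(years)) years <- sort(unique(d$year))

  beta <- stats::coef(fit)
  # saturated designs have zero residual variance; the SEs are then 0 and
  # summary()'s perfect-fit warning is expected
  Vb <- suppressWarnings(stats::vcov(fit))
  tt <- stats::delete.response(stats::terms(fit))
  # saturated designs: SEs are zero and the interval collapses to the point
  z <- if (fit$df.residual > 0) stats::qt(1 - (1 - conf) / 2,
                                          fit$df.residual) else 0
  est <- se <- rep(NA_real_, length(years))
  for (j in seq_along(years)) {
    if (!as.character(years[j]) %in% levels(d$fyear)) next
    nd <- data.frame(eff = levels(d$eff),
                     fyear = factor(as.character(years[j]),
                                    levels = levels(d$fyear)))
    X <- stats::model.matrix(tt, nd, xlev = fit$xlevels)
    cvec <- colMeans(X)  # equal-weight average over effect levels
    est[j] <- sum(cvec * beta)
    se[j] <- sqrt(drop(t(cvec) %*% Vb %*% cvec))
  }
  out <- data.frame(year = years, pike_lsmean = est, se = se,
                    ci_lo = pmax(est - z * se, 0),
                    ci_hi = pmin(est + z * se, 1))
  res <- stats::resid(fit)
  attr(out, "fit") <- fit
  attr(out, "diagnostics") <- list(
    shapiro_p = if (length(res) >= 3 && length(res) <= 5000 &&
                    stats::sd(res) > 0) {
      stats::shapiro.test(res)$p.value
    } else NA_real_,
    lag1_autocor = if (length(res) > 2 && stats::sd(res) > 0) {
      stats::cor(res[-1], res[-length(res)])
    } else NA_real_
  )
  class(out) <- c("ls_means_result", "data.frame")
  out
}

#' Percent change between two years of a baseline series
#'
#' `100 * (pike[from] - pike[to]) / pike[from]`: positive values are
#' reductions.
#'
#' @param result an [fit_ls_means()] result (or any data frame with `year`
#'   and `pike_lsmean`).
#' @param from_year,to_year years to compare; both must be estimated.
#' @return percent change (scalar).
#' @export
percent_change <- function(result, from_year, to_year) {
  v_from <- result$pike_lsmean[match(from_year, result$year)]
  v_to <- result$pike_lsmean[match(to_year, result$year)]
  if (is.na(v_from) || is.na(v_to)) stop("both years must be estimated")
  if (v_from == 0) stop("undefined: baseline value at from_year is 0")
  100 * (v_from - v_to) / v_from
}
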