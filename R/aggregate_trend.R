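# Population-weighted aggregation of per-site sPIKE into regional and
# continental series, and period-specific trend tests.
#
#   r_t = sum_i w_{i,t} s_{i,t},   w_{i,t} = E_{i,t} / sum_i E_{i,t}
#   V(logit(r_t)) = sum_i w_{i,t}^2 V(logit(s_{i,t}))
#   95% CI = inv_logit( logit(r_t) +/- z_{0.975} sqrt(V(logit(r_t))) )
#
# Weighting by live-elephant population (not by carcasses found) makes r_t an
# index of the proportion of the region's elephants subject to poaching, and
# keeps a site's influence from fluctuating with its year-to-year search
# effort.

#' Population-based aggregation weights for one year
#'
#' @param populations named list of `population_schedule` objects.
#' @param site_ids sites to include.
#' @param year the year.
#' @return named numeric vector of weights, proportional to the interpolated
#'   live-elephant estimates and summing to 1.
#' @export
compute_weights <- function(populations, site_ids, year) {
  E <- vapply(site_ids, function(id) {
    p <- populations[[id]]
    if (is.null(p)) stop("no population schedule for site '", id, "'")
    i <- match(year, p$years)
    if (is.na(i)) stop("year ", year, " outside schedule for site '", id, "'")
    p$E[i]
  }, numeric(1))
  if (sum(E) <= 0) stop("all-zero populations in year ", year)
  E / sum(E)
}

#' Weighted regional (or continental) sPIKE series
#'
#' @param posteriors named list of `state_posterior` objects (the smoother
#'   fills unobserved years, so every site contributes in every year).
#' @param populations named list of `population_schedule` objects.
#' @param site_ids sites to aggregate; default all fitted sites.
#' @param label scope label, e.g. a region name or `"continent"`.
#' @param conf confidence level for the back-transformed interval.
#' @return an object of class `regional_series`: data frame with columns
#'   `year, r, V_logit, ci_lo, ci_hi`; the per-site-year weight matrix is
#'   attached as attribute `weights`.
#' @export
regional_spike <- function(posteriors, populations,
                           site_ids = names(posteriors),
                           label = "continent", conf = 0.95) {
  if (length(site_ids) == 0L) stop("no sites to aggregate")
  fits <- posteriors[site_ids]
  if (any(vapply(fits, is.null, logical(1)))) {
    stop("missing posterior for site(s): ",
         paste(site_ids[vapply(fits, is.null, logical(1))], collapse = ", "))
  }
  years <- fits[[1]]$years
  z <- stats::qnorm(1 - (1 - conf) / 2)
  Wmat <- matrix(NA_real_, nrow = length(site_ids), ncol = length(years),
                 dimnames = list(site_ids, years))
  r <- V_logit <- numeric(length(years))
  for (j in seq_along(years)) {
    w <- compute_weights(populations, site_ids, years[j])
    Wmat[, j] <- w
    s <- vapply(fits, function(f) f$s[j], numeric(1))
    V <- vapply(fits, function(f) f$V[j], numeric(1))
    r[j] <- sum(w * s)
    V_logit[j] <- sum(w^2 * V)
  }
  out <- data.frame(
    year = years, r = r, V_logit = V_logit,
    ci_lo = inv_logit(logit(r) - z * sqrt(V_logit)),
    ci_hi = inv_logit(logit(r) + z * sqrt(V_logit))
  )
  attr(out, "weights") <- Wmat
  attr(out, "label") <- label
  class(out) <- c("regional_series", "data.frame")
  out
}

#' Period trend in a weighted sPIKE series by feasible GLS
#'
#' Regresses the aggregated series `r_t` on year over the period, on the
#' probability scale. Two-step FGLS: an OLS fit supplies the residual
#' variance; each year's total error variance is then the residual variance
#' plus the delta-method sampling variance of `r_t`
#' (`V(logit(r_t)) * [r_t (1 - r_t)]^2`), and the final fit is weighted least
#' squares with inverse total variances. With equal sampling variances this
#' reduces to OLS. The slope's t test uses `n - 2` degrees of freedom.
#'
#' @param series a [regional_spike()] result.
#' @param period length-2 year range, e.g. `c(2011, 2018)`.
#' @param scale `"probability"` (as reported) or `"logit"`.
#' @return an object of class `trend_fit`: one-row data frame with `region`,
#'   `period`, `slope` (per year), `se`, `t_stat`, `df`, `p_value`, and
#'   placeholders for Bonferroni flags (see [bonferroni_adjust()]).
#' @export
fgls_trend <- function(series, period, scale = c("probability", "logit")) {
  scale <- match.arg(scale)
  d <- series[series$year >= period[1] & series$year <= period[2], ]
  if (nrow(d) < 3L) stop("need >= 3 years in the trend period")
  if (length(unique(d$year)) < 2L) stop("singular design: constant year")
  if (scale == "probability") {
    y <- d$r
    samp_var <- d$V_logit * (d$r * (1 - d$r))^2  # delta method to prob scale
  } else {
    y <- logit(d$r)
    samp_var <- d$V_logit
  }
  x <- d$year
  ols <- stats::lm(y ~ x)
  s2_res <- sum(stats::resid(ols)^2) / ols$df.residual
  total_var <- s2_res + samp_var
  wls <- stats::lm(y ~ x, weights = 1 / total_var)
  co <- summary(wls)$coefficients
  slope <- co["x", "Estimate"]
  se <- co["x", "Std. Error"]
  df <- wls$df.residual
  t_stat <- slope / se
  p <- 2 * stats::pt(-abs(t_stat), df)
  structure(
    data.frame(region = attr(series, "label") %||% "series",
               period = paste(period[1], period[2], sep = "-"),
               slope = slope, se = se, t_stat = t_stat, df = df,
               p_value = p, bonferroni_significant = NA, m_tests = NA_integer_),
    class = c("trend_fit", "data.frame")
  )
}

#' Bonferroni flagging of a family of trend tests
#'
#' Marks each fit significant iff `p < alpha_family / m`, controlling the
#' family-wise error rate at `alpha_family`.
#'
#' @param fits a `trend_fit` or data frame of stacked trend fits.
#' @param alpha_family family-wise error rate (default 0.05).
#' @param m family size; default the number of fits supplied. The headline
#'   analysis uses m = 10 (5 scopes x 2 periods).
#' @return `fits` with `bonferroni_significant` and `m_tests` filled in.
#' @export
bonferroni_adjust <- function(fits, alpha_family = 0.05, m = nrow(fits)) {
  stopifnot(m >= 1)
  fits$bonferroni_significant <- fits$p_value < alpha_family / m
  fits$m_tests <- as.integer(m)
  fits
}

#' Continental series and trend excluding one region
#'
#' Re-aggregates and re-tests the continental series over the complement of
#' one region's sites, to ask whether a continental trend is carried by a
#' single region.
#'
#' @inheritParams regional_spike
#' @param exclude region label to drop.
#' @param period year range for the trend test.
#' @return list with the `regional_series` and the `trend_fit`.
#' @export
continental_excluding_region <- function(posteriors, populations, exclude,
                                         period = c(2011L, 2018L)) {
  keep <- names(posteriors)[vapply(posteriors, function(f) {
    !identical(f$region, exclude)
  }, logical(1))]
  series <- regional_spike(posteriors, populations, keep,
                           label = paste0("continent-excl-", exclude))
  list(series = series, trend = fgls_trend(series, period))
}
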