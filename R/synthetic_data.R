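# Simulated carcass datasets with the statistical structure the analysis
# assumes, and RMSE scoring of the estimator against the known truth
# ("aPIKE"). Two truth-generating schemes are provided:
#   * trend:  per-site logit-linear trend with annual deviations,
#       logit(a_{i,1}) ~ U(-4, 4),  beta_i ~ U(-1, 1),
#       logit(a_{i,t>1}) = logit(a_{i,1}) + beta_i (t - 1) + N(0, 1)
#   * random: a_{i,t} ~ U(0, 1) independently, no structure at all.
# Observed counts are binomial draws K ~ Binomial(C, a) on a fixed template
# of per-site-year carcass totals and missingness. The default template
# emulates the MIKE monitoring network: 38 sites in 4 regions with
# region-specific carcass rates, live-elephant populations and
# reporting completeness.

#' Specification of the logit-linear-trend truth scheme
#'
#' @param n_sites,n_years template dimensions (defaults 38 sites, 16 years).
#' @param start_logit_range uniform range for the year-1 logit truth.
#' @param slope_range uniform range for the per-site logit-scale slope
#'   (per year).
#' @param noise_sd standard deviation of the annual deviation from the
#'   trendline (logit scale).
#' @return an object of class `trend_sim_spec`.
#' @export
trend_sim_spec <- function(n_sites = 38L, n_years = 16L,
                           start_logit_range = c(-4, 4),
                           slope_range = c(-1, 1), noise_sd = 1) {
  stopifnot(n_sites >= 1, n_years >= 1, noise_sd >= 0)
  structure(list(n_sites = n_sites, n_years = n_years,
                 start_logit_range = start_logit_range,
                 slope_range = slope_range, noise_sd = noise_sd),
            class = "trend_sim_spec")
}

#' Specification of the structureless uniform-random truth scheme
#'
#' @inheritParams trend_sim_spec
#' @return an object of class `random_sim_spec`.
#' @export
random_sim_spec <- function(n_sites = 38L, n_years = 16L) {
  stopifnot(n_sites >= 1, n_years >= 1)
  structure(list(n_sites = n_sites, n_years = n_years),
            class = "random_sim_spec")
}

#' Specification of the MIKE-like sampling template
#'
#' Defaults calibrated to the monitoring network's per-region summary
#' statistics: site counts, mean (and range of) carcasses reported per
#' site-year, mean (and range of) estimated live elephants, and mean
#' reported years in the pre- and post-2011 sub-periods.
#'
#' @param region_sites named integer vector of sites per region.
#' @param mean_carcasses,carcass_range per-region mean and (lo, hi) range of
#'   the per-site carcass rate (carcasses per year).
#' @param mean_elephants,elephant_range per-region mean and range of
#'   per-site live-elephant population.
#' @param mean_years_pre,mean_years_post per-region mean number of reported
#'   years in 2003-2011 and 2011-2018.
#' @param window study window.
#' @param prob_observe_split probability that the split year (2011) itself is
#'   reported; reconciles the sub-period means with the total.
#' @param surveys_per_site range of synthetic population-survey points per
#'   site.
#' @return an object of class `mike_like_spec`.
#' @export
mike_like_spec <- function(
    region_sites = c(Central = 12L, Eastern = 10L, Southern = 9L, West = 7L),
    mean_carcasses = c(Central = 17.8, Eastern = 51.0, Southern = 46.1,
                       West = 7.5),
    carcass_range = list(Central = c(5.7, 59.0), Eastern = c(3.8, 187.7),
                         Southern = c(12.5, 130.1), West = c(3.1, 17.4)),
    mean_elephants = c(Central = 3529, Eastern = 6559, Southern = 8078,
                       West = 492),
    elephant_range = list(Central = c(213, 18844), Eastern = c(105, 20619),
                          Southern = c(1338, 27802), West = c(35, 1003)),
    mean_years_pre = c(Central = 7.3, Eastern = 8.3, Southern = 7.9,
                       West = 5.9),
    mean_years_post = c(Central = 6.8, Eastern = 7.5, Southern = 8.0,
                        West = 6.6),
    window = c(2003L, 2018L), prob_observe_split = 0.9,
    surveys_per_site = c(1L, 5L)) {
  stopifnot(all(names(region_sites) %in% mike_regions()))
  structure(list(region_sites = region_sites,
                 mean_carcasses = mean_carcasses,
                 carcass_range = carcass_range,
                 mean_elephants = mean_elephants,
                 elephant_range = elephant_range,
                 mean_years_pre = mean_years_pre,
                 mean_years_post = mean_years_post,
                 window = window, prob_observe_split = prob_observe_split,
                 surveys_per_site = surveys_per_site),
            class = "mike_like_spec")
}

# Lognormal draw with target mean m and a plausibility range (lo, hi):
# sdlog from the log-range spread, meanlog mean-matched, draws clamped.
rlnorm_calibrated <- function(n, m, range) {
  sdlog <- (log(range[2]) - log(range[1])) / 4
  x <- stats::rlnorm(n, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
  pmin(pmax(x, range[1]), range[2])
}

#' Generate a MIKE-like sampling template
#'
#' Draws the fixed structure on which truth schemes are simulated: per-site
#' carcass totals `C` for reported years (Poisson around a lognormal per-site
#' rate), a missingness mask matching the per-region reporting-completeness
#' targets (every site satisfies the default 4/4 inclusion policy by
#' construction), and live-elephant population schedules built from 1-5
#' synthetic survey points per site via [interpolate_populations()].
#'
#' @param spec a [mike_like_spec()].
#' @param missingness if `FALSE`, every site-year is reported.
#' @return list with `sites` (per site: `site_id`, `region`, `years`, `C`
#'   with `NA` at unreported years, `observed` mask), `populations` (named
#'   list of `population_schedule`), `surveys` (the raw synthetic survey
#'   table), and the `spec`.
#' @export
generate_mike_like_template <- function(spec = mike_like_spec(),
                                        missingness = TRUE) {
  years <- seq.int(spec$window[1], spec$window[2])
  split <- 2011L
  pre_pool <- years[years < split]
  post_pool <- years[years > split]
  sites <- list()
  surveys <- list()
  for (region in names(spec$region_sites)) {
    n <- spec$region_sites[[region]]
    lambda <- rlnorm_calibrated(n, spec$mean_carcasses[[region]],
                                spec$carcass_range[[region]])
    pop <- rlnorm_calibrated(n, spec$mean_elephants[[region]],
                             spec$elephant_range[[region]])
    for (k in seq_len(n)) {
      id <- sprintf("%s_%02d", region, k)
      if (missingness) {
        n_pre <- max(4L, min(length(pre_pool) + 1L,
                             round(stats::rnorm(1, spec$mean_years_pre[[region]],
                                                1.3))))
        n_post <- max(4L, min(length(post_pool) + 1L,
                              round(stats::rnorm(1, spec$mean_years_post[[region]],
                                                 1.3))))
        obs_split <- n_pre == length(pre_pool) + 1L ||
          n_post == length(post_pool) + 1L ||
          stats::runif(1) < spec$prob_observe_split
        obs_years <- c(
          if (obs_split) split,
          sample(pre_pool, n_pre - obs_split),
          sample(post_pool, n_post - obs_split)
        )
      } else {
        obs_years <- years
      }
      observed <- years %in% obs_years
      C <- rep(NA_integer_, length(years))
      C[observed] <- stats::rpois(sum(observed), lambda[k])
      sites[[id]] <- list(site_id = id, region = region, years = years,
                          C = C, observed = observed)
      n_surv <- sample(seq(spec$surveys_per_site[1], spec$surveys_per_site[2]),
                       1L)
      surveys[[id]] <- data.frame(
        site_id = id,
        year = sort(sample(years, n_surv)),
        estimate = pop[k] * exp(stats::rnorm(n_surv, 0, 0.15))
      )
    }
  }
  surveys <- do.call(rbind, c(surveys, list(make.row.names = FALSE)))
  list(sites = sites,
       populations = interpolate_populations(surveys, spec$window),
       surveys = surveys, spec = spec)
}

# Shared machinery: drop truth onto a template, draw binomial counts.
template_to_series <- function(template, apike) {
  mapply(function(site, a) {
    K <- rep(NA_integer_, length(site$years))
    i <- which(site$observed)
    K[i] <- stats::rbinom(length(i), site$C[i], a[i])
    site_series(site$site_id, site$region, site$years, site$C, K)
  }, template$sites, asplit(apike, 1), SIMPLIFY = FALSE)
}

check_template_dims <- function(spec, template) {
  n_years <- length(template$sites[[1]]$years)
  if (length(template$sites) != spec$n_sites || n_years != spec$n_years) {
    stop("template dimensions (", length(template$sites), " x ", n_years,
         ") do not match spec (", spec$n_sites, " x ", spec$n_years, ")")
  }
}

#' Simulate a carcass dataset with logit-linear-trend truth
#'
#' @param spec a [trend_sim_spec()].
#' @param template a [generate_mike_like_template()] result supplying the
#'   carcass totals and missingness mask.
#' @return list with `series` (named list of [site_series()]; site-years
#'   missing in the template are missing here too), `apike` (sites x years
#'   truth matrix, all years), `start_logit`, `beta`.
#' @export
simulate_trend_dataset <- function(spec = trend_sim_spec(), template) {
  check_template_dims(spec, template)
  tt <- seq_len(spec$n_years)
  start <- stats::runif(spec$n_sites, spec$start_logit_range[1],
                        spec$start_logit_range[2])
  beta <- stats::runif(spec$n_sites, spec$slope_range[1], spec$slope_range[2])
  x <- outer(start, rep(1, spec$n_years)) + outer(beta, tt - 1)
  # annual deviations from the trendline apply to years after the first
  if (spec$n_years > 1L) {
    x[, -1] <- x[, -1] + matrix(stats::rnorm(spec$n_sites * (spec$n_years - 1),
                                             0, spec$noise_sd),
                                nrow = spec$n_sites)
  }
  apike <- clamp_prob(inv_logit(x), 1e-6)
  rownames(apike) <- names(template$sites)
  list(series = template_to_series(template, apike), apike = apike,
       start_logit = start, beta = beta)
}

#' Simulate a carcass dataset with structureless uniform truth
#'
#' @param spec a [random_sim_spec()].
#' @inheritParams simulate_trend_dataset
#' @return as [simulate_trend_dataset()], without slope terms.
#' @export
simulate_random_dataset <- function(spec = random_sim_spec(), template) {
  check_template_dims(spec, template)
  apike <- matrix(stats::runif(spec$n_sites * spec$n_years),
                  nrow = spec$n_sites,
                  dimnames = list(names(template$sites), NULL))
  apike <- clamp_prob(apike, 1e-6)
  list(series = template_to_series(template, apike), apike = apike)
}

#' Score one simulation replicate against the known truth
#'
#' @param apike truth matrix (sites x years) from a simulate function.
#' @param posteriors named list of `state_posterior` fits for the same sites.
#' @param populations named list of `population_schedule` (the aggregation
#'   weights' source).
#' @return list with `rmse_site_years` (root-mean over all site-years of the
#'   squared sPIKE error), `rmse_by_site` (per-site RMSE averaged over
#'   sites), `rmse_continental` (RMSE over years between the
#'   population-weighted continental sPIKE and the population-weighted
#'   continental truth), `mean_sigma2` (mean ML process error across sites;
#'   heavy-tailed whenever sites saturate a probability boundary), and
#'   `median_sigma2` (the typical site's process error, robust to that
#'   tail).
#' @export
score_simulation <- function(apike, posteriors, populations) {
  ids <- rownames(apike)
  s_hat <- t(vapply(posteriors[ids], function(f) f$s,
                    numeric(ncol(apike))))
  err2 <- (s_hat - apike)^2
  years <- posteriors[[1]]$years
  r_hat <- r_true <- numeric(length(years))
  for (j in seq_along(years)) {
    w <- compute_weights(populations, ids, years[j])
    r_hat[j] <- sum(w * s_hat[, j])
    r_true[j] <- sum(w * apike[, j])
  }
  s2 <- vapply(posteriors[ids], function(f) as.numeric(f$sigma2_hat),
               numeric(1))
  list(rmse_site_years = sqrt(mean(err2)),
       rmse_by_site = mean(sqrt(rowMeans(err2))),
       rmse_continental = sqrt(mean((r_hat - r_true)^2)),
       mean_sigma2 = mean(s2),
       median_sigma2 = stats::median(s2))
}
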