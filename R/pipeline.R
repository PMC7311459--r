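# End-to-end orchestration: ingest -> filter -> per-site fits -> weighted
# aggregation -> trend tests -> baseline comparison -> diagnostics, plus the
# simulation study and the inclusion-threshold sensitivity analysis. All
# randomness is routed through an explicit seed; given fixed inputs and seed
# every artifact is deterministic.

#' Pipeline configuration
#'
#' @param window study window (years).
#' @param policy inclusion [filter_policy()].
#' @param ssm an [ssm_config()].
#' @param periods list of year ranges for the trend regressions; the default
#'   splits at the 2011 poaching-rate inflection.
#' @param alpha_family family-wise error rate for the Bonferroni correction.
#' @param m_tests Bonferroni family size; default 10 = 5 scopes (continent +
#'   4 regions) x 2 periods.
#' @param out_dir optional directory for CSV artifacts and the run log.
#' @param seed integer seed for any stochastic stage.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(window = c(2003L, 2018L),
                            policy = filter_policy(),
                            ssm = ssm_config(),
                            periods = list(c(2003L, 2010L), c(2011L, 2018L)),
                            alpha_family = 0.05, m_tests = 10L,
                            out_dir = NULL, seed = 1L) {
  for (p in periods) {
    if (p[1] < window[1] || p[2] > window[2]) {
      stop("trend period ", p[1], "-", p[2], " outside the study window")
    }
  }
  structure(list(window = window, policy = policy, ssm = ssm,
                 periods = periods, alpha_family = alpha_family,
                 m_tests = as.integer(m_tests), out_dir = out_dir,
                 seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognised keys (all optional, defaults as in [pipeline_config()]):
#' `window: [first, last]`, `filter: {split_year, min_pre, min_post}`,
#' `periods: [[a, b], [c, d]]`, `alpha_family`, `m_tests`, `out_dir`, `seed`.
#'
#' @param path YAML file path.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading config files requires the 'yaml' package")
  }
  cfg <- yaml::read_yaml(path)
  defaults <- pipeline_config()
  fp <- defaults$policy
  if (!is.null(cfg$filter)) {
    fp <- filter_policy(cfg$filter$split_year %||% fp$split_year,
                        cfg$filter$min_pre %||% fp$min_pre,
                        cfg$filter$min_post %||% fp$min_post)
  }
  pipeline_config(
    window = as.integer(cfg$window %||% defaults$window),
    policy = fp,
    periods = if (is.null(cfg$periods)) defaults$periods else {
      lapply(cfg$periods, as.integer)
    },
    alpha_family = cfg$alpha_family %||% defaults$alpha_family,
    m_tests = cfg$m_tests %||% defaults$m_tests,
    out_dir = cfg$out_dir,
    seed = cfg$seed %||% defaults$seed
  )
}

#' Run the full trend analysis
#'
#' Filters sites by the inclusion policy, fits the state-space model to every
#' retained site, aggregates sPIKE into one continental and four regional
#' series, tests the period trends with Bonferroni flagging, re-tests the
#' continent excluding Eastern Africa, fits the carcass-weighted
#' least-squares-means baseline, and collects fit diagnostics.
#'
#' @param series named list of [site_series()] (e.g. from
#'   [read_carcass_table()] or a simulation).
#' @param populations named list of `population_schedule` (e.g. from
#'   [interpolate_populations()]).
#' @param config a [pipeline_config()].
#' @return a result bundle (class `pike_analysis`): `fits`, `regional` (named
#'   list of `regional_series`, continent first), `trends` (stacked
#'   `trend_fit` table with Bonferroni flags), `excl_eastern` (series + trend),
#'   `baseline` (LS-means result with `percent_change_2011_2018`),
#'   `diagnostics`, `n_sites`, `config`.
#' @export
run_analysis <- function(series, populations, config = pipeline_config()) {
  kept <- filter_sites(series, config$policy)
  if (length(kept) == 0L) stop("[filter] no sites pass the inclusion policy")
  fits <- fit_sites(kept, config$ssm)

  scopes <- list(continent = names(fits))
  for (region in mike_regions()) {
    ids <- names(fits)[vapply(fits, function(f) f$region == region,
                              logical(1))]
    if (length(ids)) scopes[[region]] <- ids
  }
  regional <- mapply(function(ids, label) {
    regional_spike(fits, populations, ids, label = label)
  }, scopes, names(scopes), SIMPLIFY = FALSE)

  trends <- do.call(rbind, unlist(lapply(regional, function(sr) {
    lapply(config$periods, function(p) fgls_trend(sr, p))
  }), recursive = FALSE))
  rownames(trends) <- NULL
  trends <- bonferroni_adjust(trends, config$alpha_family, config$m_tests)

  excl_eastern <- if ("Eastern" %in% trends$region) {
    continental_excluding_region(fits, populations, "Eastern",
                                 period = config$periods[[length(config$periods)]])
  }

  baseline <- fit_ls_means(write_carcass_table(kept),
                           years = seq.int(config$window[1], config$window[2]))
  pc <- tryCatch(percent_change(baseline, 2011L, 2018L), error = function(e) NA)

  bundle <- structure(
    list(fits = fits, regional = regional, trends = trends,
         excl_eastern = excl_eastern,
         baseline = baseline, percent_change_2011_2018 = pc,
         diagnostics = model_fit_correlation(fits),
         n_sites = length(kept), config = config),
    class = "pike_analysis"
  )
  if (!is.null(config$out_dir)) write_analysis_artifacts(bundle, config$out_dir)
  bundle
}

#' @export
print.pike_analysis <- function(x, ...) {
  cat("<pike_analysis> ", x$n_sites, " sites; fit r = ",
      format(x$diagnostics$pearson_r, digits = 3), "\n", sep = "")
  print(format_trend_table(x$trends))
  invisible(x)
}

#' Format a trend table for reporting
#'
#' @param trends a stacked `trend_fit` data frame with Bonferroni flags.
#' @return data frame with `estimate_se` formatted as `slope +/- SE` and a
#'   significance marker.
#' @export
format_trend_table <- function(trends) {
  data.frame(
    region = trends$region, period = trends$period,
    estimate_se = sprintf("%.3f ± %.3f", trends$slope, trends$se),
    t = round(trends$t_stat, 2),
    P = signif(trends$p_value, 2),
    significant = ifelse(trends$bonferroni_significant, "*", "")
  )
}

write_analysis_artifacts <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(posteriors_to_table(bundle$fits),
                   file.path(out_dir, "site_fits.csv"), row.names = FALSE)
  reg <- do.call(rbind, lapply(names(bundle$regional), function(nm) {
    cbind(scope = nm, as.data.frame(bundle$regional[[nm]]))
  }))
  utils::write.csv(reg, file.path(out_dir, "regional_series.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$trends, file.path(out_dir, "trends.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(bundle$baseline),
                   file.path(out_dir, "baseline_ls_means.csv"),
                   row.names = FALSE)
  writeLines(c(
    sprintf("spikessm %s on R %s.%s",
            as.character(utils::packageVersion("spikessm")),
            R.version$major, R.version$minor),
    sprintf("window %d-%d; inclusion >=%d/%d years around %d; m_tests %d",
            bundle$config$window[1], bundle$config$window[2],
            bundle$config$policy$min_pre, bundle$config$policy$min_post,
            bundle$config$policy$split_year, bundle$config$m_tests),
    sprintf("sites retained: %d", bundle$n_sites),
    sprintf("sites with sigma2 at a search bound: %d",
            sum(vapply(bundle$fits, function(f) isTRUE(f$bound_hit),
                       logical(1)))),
    sprintf("model fit r: %.4f", bundle$diagnostics$pearson_r),
    sprintf("mean sigma2_hat: %.4f",
            mean(vapply(bundle$fits, function(f) as.numeric(f$sigma2_hat),
                        numeric(1)))),
    sprintf("baseline percent change 2011-2018: %.2f",
            bundle$percent_change_2011_2018),
    utils::capture.output(print(format_trend_table(bundle$trends)))
  ), file.path(out_dir, "run_log.txt"))
  invisible(bundle)
}

#' Sensitivity of the continental series to the inclusion threshold
#'
#' Re-filters, re-fits and re-aggregates the continental series for each
#' minimum-years threshold (applied to both sub-periods), and reports the
#' maximum absolute deviation of each series from the first threshold's.
#'
#' @param series named list of [site_series()].
#' @param populations named list of `population_schedule`.
#' @param minima integer vector of thresholds to try.
#' @param config a [pipeline_config()].
#' @return list with `continental` (one `regional_series` per threshold),
#'   `n_sites` per threshold, and `max_abs_dev` relative to the first
#'   threshold's series.
#' @export
run_sensitivity <- function(series, populations, minima = 2:6,
                            config = pipeline_config()) {
  runs <- lapply(minima, function(m) {
    kept <- filter_sites(series, filter_policy(config$policy$split_year, m, m))
    if (length(kept) == 0L) return(NULL)
    fits <- fit_sites(kept, config$ssm)
    list(n = length(kept),
         series = regional_spike(fits, populations, label = "continent"))
  })
  names(runs) <- paste0("min_", minima)
  ok <- !vapply(runs, is.null, logical(1))
  ref <- runs[[which(ok)[1]]]$series$r
  list(
    continental = lapply(runs[ok], `[[`, "series"),
    n_sites = vapply(runs[ok], `[[`, integer(1), "n"),
    max_abs_dev = vapply(runs[ok], function(x) max(abs(x$series$r - ref)),
                         numeric(1))
  )
}

#' Simulation study of estimator accuracy
#'
#' Generates `replicates` datasets under the chosen truth scheme on a fixed
#' MIKE-like template, fits the state-space model to every site of every
#' replicate, and scores sPIKE against the known truth by RMSE.
#'
#' @param scheme `"trend"` (logit-linear trends) or `"random"`
#'   (structureless uniform truth).
#' @param replicates number of simulated datasets.
#' @param template fixed sampling template; generated from `template_spec`
#'   when `NULL` (one template is shared by all replicates).
#' @param template_spec a [mike_like_spec()].
#' @param sim_spec a [trend_sim_spec()] or [random_sim_spec()]; default
#'   matches the template dimensions.
#' @param ssm an [ssm_config()].
#' @param seed master seed; per-replicate streams are spawned from it.
#' @return an object of class `sim_score`: means and ranges over replicates
#'   of the continental RMSE, the site-level RMSE (both the root-mean over
#'   all site-years and the per-site-averaged ordering), and the mean ML
#'   process error; plus per-replicate values.
#' @export
run_simulation_study <- function(scheme = c("trend", "random"),
                                 replicates = 100L, template = NULL,
                                 template_spec = mike_like_spec(),
                                 sim_spec = NULL, ssm = ssm_config(),
                                 seed = 1L) {
  scheme <- match.arg(scheme)
  set.seed(seed)
  if (is.null(template)) template <- generate_mike_like_template(template_spec)
  n_sites <- length(template$sites)
  n_years <- length(template$sites[[1]]$years)
  if (is.null(sim_spec)) {
    sim_spec <- if (scheme == "trend") {
      trend_sim_spec(n_sites, n_years)
    } else {
      random_sim_spec(n_sites, n_years)
    }
  }
  rep_seeds <- sample.int(.Machine$integer.max - 1L, replicates)
  per_rep <- lapply(seq_len(replicates), function(r) {
    set.seed(rep_seeds[r])
    sim <- if (scheme == "trend") {
      simulate_trend_dataset(sim_spec, template)
    } else {
      simulate_random_dataset(sim_spec, template)
    }
    fits <- fit_sites(sim$series, ssm)
    score_simulation(sim$apike, fits, template$populations)
  })
  metric <- function(name) vapply(per_rep, `[[`, numeric(1), name)
  structure(list(
    scheme = scheme, n_replicates = replicates,
    rmse_continental = mean(metric("rmse_continental")),
    rmse_continental_range = range(metric("rmse_continental")),
    rmse_site_years = mean(metric("rmse_site_years")),
    rmse_site_years_range = range(metric("rmse_site_years")),
    rmse_by_site = mean(metric("rmse_by_site")),
    mean_sigma2 = mean(metric("mean_sigma2")),
    median_sigma2 = mean(metric("median_sigma2")),
    per_replicate = data.frame(
      replicate = seq_len(replicates),
      rmse_continental = metric("rmse_continental"),
      rmse_site_years = metric("rmse_site_years"),
      rmse_by_site = metric("rmse_by_site"),
      mean_sigma2 = metric("mean_sigma2"),
      median_sigma2 = metric("median_sigma2")
    )
  ), class = "sim_score")
}

#' @export
print.sim_score <- function(x, ...) {
  cat("<sim_score> scheme = ", x$scheme, ", ", x$n_replicates,
      " replicates\n", sep = "")
  cat(sprintf("  continental RMSE: %.3f (%.3f-%.3f)\n",
              x$rmse_continental, x$rmse_continental_range[1],
              x$rmse_continental_range[2]))
  cat(sprintf("  site-level RMSE:  %.3f (%.3f-%.3f)\n",
              x$rmse_site_years, x$rmse_site_years_range[1],
              x$rmse_site_years_range[2]))
  cat(sprintf("  mean process error: %.2f\n", x$mean_sigma2))
  invisible(x)
}
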