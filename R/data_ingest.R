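# Reading, validation and preparation of carcass-count and population-survey
# tables. The internal data model is:
#   * site_series: one site's annual (C, K) counts on the full study window,
#     with NA where the site did not report,
#   * population_schedule: one site's interpolated live-elephant estimate for
#     every window year.
# Canonical CSV schema for carcass tables:
#   site_id, region, year, total_carcasses, illegal_carcasses
# and for survey tables: site_id, year, estimate.

#' Construct a site series
#'
#' One monitoring site's annual carcass record on the full study window:
#' total carcasses found `C` and illegally killed carcasses `K`, with `NA`
#' marking years the site did not report. A year counts as observed when both
#' `C` and `K` are present; a reported year with `C = 0` is observed but
#' carries no information about the proportion killed.
#'
#' @param site_id character site identifier.
#' @param region one of `mike_regions()`.
#' @param years integer vector of consecutive calendar years (the window).
#' @param C integer vector of total carcasses per year (`NA` = not reported).
#' @param K integer vector of illegally killed carcasses per year.
#' @return an object of class `site_series`.
#' @export
site_series <- function(site_id, region, years, C, K) {
  if (!region %in% mike_regions()) {
    stop("unknown region '", region, "' for site '", site_id, "'")
  }
  years <- as.integer(years)
  if (any(diff(years) != 1L)) stop("years must be consecutive")
  if (length(C) != length(years) || length(K) != length(years)) {
    stop("C and K must have one entry per window year")
  }
  if (any(stats::complete.cases(C, K) & (K > C | K < 0 | C < 0))) {
    stop("site '", site_id, "': need 0 <= K <= C in every observed year")
  }
  if (any(is.na(C) != is.na(K))) {
    stop("site '", site_id, "': C and K must be missing together")
  }
  structure(
    list(site_id = as.character(site_id), region = region, years = years,
         C = as.integer(C), K = as.integer(K),
         observed = !is.na(C) & !is.na(K)),
    class = "site_series"
  )
}

#' @export
print.site_series <- function(x, ...) {
  cat("<site_series> ", x$site_id, " (", x$region, "), ",
      sum(x$observed), "/", length(x$years), " years observed\n", sep = "")
  invisible(x)
}

#' Read a carcass-count table
#'
#' Reads the canonical CSV (`site_id, region, year, total_carcasses,
#' illegal_carcasses`), validates it, and returns one [site_series] per site
#' on the requested window. Years absent from the file are marked missing.
#'
#' @param path CSV file path.
#' @param window length-2 integer, first and last study year.
#' @return named list of `site_series`.
#' @export
read_carcass_table <- function(path, window = c(2003L, 2018L)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "region", "year", "total_carcasses", "illegal_carcasses")
  if (!all(need %in% names(df))) {
    stop("carcass table must have columns: ", paste(need, collapse = ", "))
  }
  carcass_records_to_series(df, window)
}

#' Convert a carcass-record data frame to site series
#'
#' @param df data frame in the canonical carcass schema.
#' @inheritParams read_carcass_table
#' @return named list of `site_series`.
#' @export
carcass_records_to_series <- function(df, window = c(2003L, 2018L)) {
  years <- seq.int(window[1], window[2])
  if (nrow(df) == 0L) return(structure(list(), names = character(0)))

  bad <- which(!stats::complete.cases(df[c("site_id", "region", "year",
                                           "total_carcasses",
                                           "illegal_carcasses")]))
  if (length(bad)) stop("malformed row(s): ", paste(bad, collapse = ", "))
  bad <- which(df$illegal_carcasses > df$total_carcasses |
                 df$illegal_carcasses < 0 | df$total_carcasses < 0)
  if (length(bad)) {
    stop("row(s) violate 0 <= illegal <= total carcasses: ",
         paste(bad, collapse = ", "))
  }
  if (anyDuplicated(df[c("site_id", "year")])) {
    dup <- df[duplicated(df[c("site_id", "year")]), , drop = FALSE]
    stop("duplicate (site, year): ",
         paste(dup$site_id, dup$year, sep = "/", collapse = ", "))
  }
  if (!all(df$region %in% mike_regions())) {
    stop("unknown region label(s): ",
         paste(unique(setdiff(df$region, mike_regions())), collapse = ", "))
  }
  if (any(df$year < window[1] | df$year > window[2])) {
    stop("rows outside the study window ", window[1], "-", window[2])
  }

  out <- lapply(split(df, df$site_id), function(d) {
    region <- unique(d$region)
    if (length(region) != 1L) {
      stop("site '", d$site_id[1], "' listed under multiple regions")
    }
    C <- K <- rep(NA_integer_, length(years))
    idx <- match(d$year, years)
    C[idx] <- d$total_carcasses
    K[idx] <- d$illegal_carcasses
    site_series(d$site_id[1], region, years, C, K)
  })
  out[order(names(out))]
}

#' Export site series back to the canonical carcass CSV
#'
#' Inverse of [read_carcass_table()]: only observed site-years are written.
#'
#' @param series named list of `site_series`.
#' @param path output CSV path; `NULL` returns the data frame only.
#' @return the canonical data frame, invisibly when written to file.
#' @export
write_carcass_table <- function(series, path = NULL) {
  rows <- lapply(series, function(s) {
    i <- which(s$observed)
    data.frame(site_id = s$site_id, region = s$region, year = s$years[i],
               total_carcasses = s$C[i], illegal_carcasses = s$K[i])
  })
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(df)) {
    df <- data.frame(site_id = character(), region = character(),
                     year = integer(), total_carcasses = integer(),
                     illegal_carcasses = integer())
  }
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' Map a raw download's columns onto the canonical carcass schema
#'
#' The public carcass-table dialect varies between releases; this converter
#' isolates the pipeline from that drift. Supply the raw data frame and a
#' named mapping from canonical names to the raw column names.
#'
#' @param df raw data frame.
#' @param mapping named character vector; names are the canonical columns
#'   (`site_id, region, year, total_carcasses, illegal_carcasses`), values
#'   the corresponding raw column names.
#' @return data frame in the canonical schema, ready for
#'   [carcass_records_to_series()].
#' @export
standardize_carcass_columns <- function(df, mapping) {
  need <- c("site_id", "region", "year", "total_carcasses",
            "illegal_carcasses")
  if (!all(need %in% names(mapping))) {
    stop("mapping must name: ", paste(need, collapse = ", "))
  }
  missing_cols <- setdiff(unname(mapping[need]), names(df))
  if (length(missing_cols)) {
    stop("raw table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  out <- df[unname(mapping[need])]
  names(out) <- need
  out
}

#' Inclusion policy for sites
#'
#' A site enters the analysis only with enough reported years on each side of
#' the split year (the poaching-trend inflection, counted in both periods).
#'
#' @param split_year year dividing the two sub-periods (default 2011).
#' @param min_pre,min_post minimum observed years required in
#'   `[window start, split_year]` and `[split_year, window end]`.
#' @return an object of class `filter_policy`.
#' @export
filter_policy <- function(split_year = 2011L, min_pre = 4L, min_post = 4L) {
  stopifnot(min_pre >= 0, min_post >= 0)
  structure(list(split_year = as.integer(split_year),
                 min_pre = as.integer(min_pre),
                 min_post = as.integer(min_post)),
            class = "filter_policy")
}

#' Filter sites by reporting completeness
#'
#' Retains exactly the sites with at least `min_pre` observed years up to and
#' including the split year and at least `min_post` from the split year on.
#' Input order is preserved; an empty result is permitted.
#'
#' @param series named list of `site_series`.
#' @param policy a [filter_policy()].
#' @return the retained subset of `series`.
#' @export
filter_sites <- function(series, policy = filter_policy()) {
  keep <- vapply(series, function(s) {
    pre <- sum(s$observed & s$years <= policy$split_year)
    post <- sum(s$observed & s$years >= policy$split_year)
    pre >= policy$min_pre && post >= policy$min_post
  }, logical(1))
  series[keep]
}

#' Read raw elephant population surveys
#'
#' Reads a CSV with columns `site_id, year, estimate` (one row per survey),
#' returning estimates grouped by site and sorted by year.
#'
#' @param path CSV file path.
#' @return data frame (site_id, year, estimate) sorted by site then year.
#' @export
read_population_surveys <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "year", "estimate")
  if (!all(need %in% names(df))) {
    stop("survey table must have columns: ", paste(need, collapse = ", "))
  }
  validate_population_surveys(df)
}

#' @keywords internal
validate_population_surveys <- function(df) {
  if (nrow(df) == 0L) {
    return(data.frame(site_id = character(), year = integer(),
                      estimate = numeric()))
  }
  if (any(df$estimate <= 0)) stop("non-positive population estimate")
  if (anyDuplicated(df[c("site_id", "year")])) {
    stop("duplicate (site, year) survey estimate")
  }
  df <- df[order(df$site_id, df$year), c("site_id", "year", "estimate")]
  rownames(df) <- NULL
  df
}

#' Interpolate population surveys onto the study window
#'
#' Linear interpolation between surveys; constant extrapolation before the
#' first and after the last survey; a single-survey site is constant across
#' all years. Weights in the regional aggregation come from these schedules.
#'
#' @param surveys data frame (site_id, year, estimate), as returned by
#'   [read_population_surveys()].
#' @param window length-2 integer year range.
#' @return named list of `population_schedule` objects, each holding `E` for
#'   every window year and `n_surveys`, the raw survey count used.
#' @export
interpolate_populations <- function(surveys, window = c(2003L, 2018L)) {
  surveys <- validate_population_surveys(surveys)
  years <- seq.int(window[1], window[2])
  out <- lapply(split(surveys, surveys$site_id), function(d) {
    if (nrow(d) == 0L) stop("site with zero surveys: '", d$site_id[1], "'")
    E <- if (nrow(d) == 1L) {
      rep(d$estimate, length(years))
    } else {
      stats::approx(d$year, d$estimate, xout = years, rule = 2)$y
    }
    structure(list(site_id = d$site_id[1], years = years, E = E,
                   n_surveys = nrow(d)),
              class = "population_schedule")
  })
  out[order(names(out))]
}
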