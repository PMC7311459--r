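test_that("carcass table round-trips through CSV unchanged", {
  set.seed(11)
  tpl <- small_template()
  sim <- simulate_random_dataset(random_sim_spec(length(tpl$sites), 16L), tpl)
  path <- withr::local_tempfile(fileext = ".csv")
  write_carcass_table(sim$series, path)
  back <- read_carcass_table(path)
  expect_identical(names(back), names(sim$series))
  for (id in names(back)) {
    expect_identical(back[[id]]$C, sim$series[[id]]$C)
    expect_identical(back[[id]]$K, sim$series[[id]]$K)
    expect_identical(back[[id]]$region, sim$series[[id]]$region)
  }
})

test_that("empty carcass table yields an empty collection without error", {
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(
    data.frame(site_id = character(), region = character(), year = integer(),
               total_carcasses = integer(), illegal_carcasses = integer()),
    path, row.names = FALSE)
  expect_length(read_carcass_table(path), 0L)
})

test_that("invalid carcass rows are rejected with informative errors", {
  base <- data.frame(site_id = "a", region = "Central", year = 2005L,
                     total_carcasses = 5L, illegal_carcasses = 2L)
  bad_k <- transform(base, illegal_carcasses = 7L)
  expect_error(carcass_records_to_series(bad_k), "illegal <= total")
  dup <- rbind(base, base)
  expect_error(carcass_records_to_series(dup), "duplicate")
  bad_region <- transform(base, region = "Atlantis")
  expect_error(carcass_records_to_series(bad_region), "region")
  outside <- transform(base, year = 1999L)
  expect_error(carcass_records_to_series(outside), "window")
})

test_that("inclusion filter counts observed years per sub-period", {
  # observed-year counts (pre, post) of (5,5), (3,8), (4,4): under a 4/4
  # policy sites 1 and 3 survive
  mk <- function(id, years_obs) {
    C <- rep(NA_integer_, 16L)
    C[match(years_obs, 2003:2018)] <- 5L
    make_series(C, ifelse(is.na(C), NA_integer_, 1L), site_id = id)
  }
  series <- list(
    a = mk("a", c(2003:2007, 2014:2018)),          # (5, 5)
    b = mk("b", c(2003, 2004, 2011:2018)),         # (3, 8): 2011 in both
    c = mk("c", c(2003:2006, 2015:2018))           # (4, 4)
  )
  kept <- filter_sites(series, filter_policy(min_pre = 4, min_post = 4))
  expect_identical(names(kept), c("a", "c"))

  # vacuous policy keeps everything; filtering is idempotent and monotone
  expect_identical(names(filter_sites(series, filter_policy(min_pre = 0,
                                                            min_post = 0))),
                   names(series))
  pol <- filter_policy(min_pre = 4, min_post = 4)
  expect_identical(filter_sites(filter_sites(series, pol), pol),
                   filter_sites(series, pol))
  n_kept <- vapply(0:9, function(m) {
    length(filter_sites(series, filter_policy(min_pre = m, min_post = m)))
  }, integer(1))
  expect_true(all(diff(n_kept) <= 0))
})

test_that("the split year counts toward both sub-periods", {
  C <- rep(NA_integer_, 16L)
  C[c(6, 7, 8, 9, 10, 11, 12)] <- 3L  # 2008-2014: 2011 is index 9
  s <- make_series(C, ifelse(is.na(C), NA_integer_, 0L))
  # pre 2003-2011 has 2008..2011 = 4 years; post 2011-2018 has 2011..2014 = 4
  expect_length(filter_sites(list(s), filter_policy(min_pre = 4,
                                                    min_post = 4)), 1L)
  expect_length(filter_sites(list(s), filter_policy(min_pre = 5,
                                                    min_post = 4)), 0L)
})

test_that("population surveys validate and round-trip", {
  df <- data.frame(site_id = c("b", "a", "a"), year = c(2010L, 2012L, 2004L),
                   estimate = c(500, 300, 100))
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  surv <- read_population_surveys(path)
  expect_identical(surv$site_id, c("a", "a", "b"))  # grouped, year-sorted
  expect_identical(surv$year, c(2004L, 2012L, 2010L))

  expect_error(read_population_surveys({
    p <- withr::local_tempfile(fileext = ".csv")
    utils::write.csv(transform(df, estimate = c(-1, 300, 100)), p,
                     row.names = FALSE)
    p
  }), "non-positive")
  expect_error(
    interpolate_populations(data.frame(site_id = "a",
                                       year = c(2004L, 2004L),
                                       estimate = c(1, 2))),
    "duplicate")
})

test_that("population interpolation is linear inside, constant outside", {
  surv <- data.frame(site_id = "a", year = c(2004L, 2008L),
                     estimate = c(100, 300))
  sched <- interpolate_populations(surv)[["a"]]
  expect_equal(sched$E[match(2006, sched$years)], 200)
  expect_equal(sched$E[match(2003, sched$years)], 100)
  expect_equal(sched$E[match(2018, sched$years)], 300)

  # a single survey is used for all years
  one <- interpolate_populations(data.frame(site_id = "a", year = 2010L,
                                            estimate = 500))[["a"]]
  expect_equal(one$E, rep(500, 16))
  expect_identical(one$n_surveys, 1L)
})

test_that("interpolation matches an independent piecewise-linear oracle", {
  surv <- data.frame(site_id = "a", year = c(2005L, 2009L, 2016L),
                     estimate = c(120, 840, 420))
  sched <- interpolate_populations(surv)[["a"]]
  # independent evaluation: explicit two-point line formula per segment
  oracle <- vapply(sched$years, function(y) {
    if (y <= 2005) return(120)
    if (y >= 2016) return(420)
    if (y <= 2009) 120 + (840 - 120) * (y - 2005) / (2009 - 2005)
    else 840 + (420 - 840) * (y - 2009) / (2016 - 2009)
  }, numeric(1))
  expect_equal(sched$E, oracle, tolerance = 1e-9)
  # survey years reproduced exactly; interior years between bracketing values
  expect_identical(sched$E[match(surv$year, sched$years)], surv$estimate)
  inside <- sched$years > 2005 & sched$years < 2009
  expect_true(all(sched$E[inside] >= 120 & sched$E[inside] <= 840))
})

test_that("raw download columns can be mapped onto the canonical schema", {
  raw <- data.frame(SiteCode = "a", Subregion = "Central", yr = 2005L,
                    TotalCarcasses = 9L, IllegalCarcasses = 3L)
  mapping <- c(site_id = "SiteCode", region = "Subregion", year = "yr",
               total_carcasses = "TotalCarcasses",
               illegal_carcasses = "IllegalCarcasses")
  std <- standardize_carcass_columns(raw, mapping)
  expect_named(std, c("site_id", "region", "year", "total_carcasses",
                      "illegal_carcasses"))
  series <- carcass_records_to_series(std)
  expect_identical(series[["a"]]$C[3], 9L)
  expect_error(standardize_carcass_columns(raw, mapping[-1]), "mapping")
  expect_error(standardize_carcass_columns(raw[-1], mapping), "lacks")
})
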