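# Shared builders for test fixtures. Everything is generated in code; no
# data files are read.

# one site's series on consecutive years starting at `start`
make_series <- function(C, K, start = 2003L, site_id = "s1",
                        region = "Central") {
  site_series(site_id, region, seq.int(start, start + length(C) - 1L), C, K)
}

# a series observed in every year, counts drawn from a logit random walk
random_walk_series <- function(W = 6L, C_range = c(10L, 50L), sigma2 = 0.5,
                               p0 = 0.5, site_id = "s1") {
  C <- sample(seq.int(C_range[1], C_range[2]), W, replace = TRUE)
  x <- stats::qlogis(p0) + c(0, cumsum(stats::rnorm(W - 1, 0, sqrt(sigma2))))
  make_series(C, stats::rbinom(W, C, stats::plogis(x)), site_id = site_id)
}

# a small MIKE-like template for fast end-to-end tests
small_template <- function(sites_per_region = c(Central = 2L, Eastern = 2L,
                                                Southern = 2L, West = 1L)) {
  generate_mike_like_template(mike_like_spec(region_sites = sites_per_region))
}

# canonical carcass data frame from a series list (observed rows only)
series_to_df <- function(series) write_carcass_table(series)
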