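# Exact smoothed posterior of the logit random-walk state by brute-force
# discretization. This is a test oracle: the forward-backward recursion is
# run over a fine mesh of logit values with the exact binomial likelihood and
# the exact Gaussian transition kernel, so no linearization is involved. It
# is O(W * n_grid^2) and intended for short series only.

#' Exact smoothed state marginals on a discretized grid
#'
#' Forward-backward recursion over a mesh of logit-state values with exact
#' binomial observation likelihoods and a Gaussian random-walk transition
#' kernel. Returns the smoothed posterior mean and variance of the logit
#' state for every year, computed by quadrature over the mesh.
#'
#' @param series a [site_series()]; short series (<= 8 years) recommended.
#' @param sigma2 process-error variance (> 0).
#' @param grid mesh of logit values; should span at least `[-10, 10]` with
#'   spacing below 0.05 (a warning is issued otherwise).
#' @param config an [ssm_config()] (initial-state prior only is used).
#' @return list with `years`, smoothed `mean` and `var` per year.
#' @export
grid_oracle <- function(series, sigma2,
                        grid = seq(-10, 10, length.out = 2001L),
                        config = ssm_config()) {
  if (sigma2 <= 0) stop("sigma2 must be positive")
  if (max(diff(grid)) > 0.05) warning("grid spacing > 0.05; mesh too coarse")
  W <- length(series$years)
  n <- length(grid)
  informative <- series$observed & !is.na(series$C) & series$C >= 1L

  # per-year observation likelihood on the grid (1 where info-free)
  lik <- matrix(1, nrow = W, ncol = n)
  for (t in which(informative)) {
    lik[t, ] <- stats::dbinom(series$K[t], series$C[t], inv_logit(grid))
  }

  # transition kernel, row-normalized so each row is a proper distribution
  # on the truncated grid
  Tm <- outer(grid, grid, function(a, b) {
    stats::dnorm(b - a, sd = sqrt(sigma2))
  })
  Tm <- Tm / rowSums(Tm)

  prior <- stats::dnorm(grid, config$init_logit_mean,
                        sqrt(config$init_logit_var))
  prior <- prior / sum(prior)

  # forward pass, normalized each step to avoid underflow
  alpha <- matrix(0, nrow = W, ncol = n)
  a <- prior * lik[1, ]
  alpha[1, ] <- a / sum(a)
  if (W > 1L) {
    for (t in 2:W) {
      a <- as.vector(alpha[t - 1L, ] %*% Tm) * lik[t, ]
      alpha[t, ] <- a / sum(a)
    }
  }

  # backward pass
  beta <- matrix(1, nrow = W, ncol = n)
  if (W > 1L) {
    for (t in (W - 1L):1L) {
      b <- as.vector(Tm %*% (lik[t + 1L, ] * beta[t + 1L, ]))
      beta[t, ] <- b / max(b)
    }
  }

  post_mean <- post_var <- numeric(W)
  for (t in seq_len(W)) {
    g <- alpha[t, ] * beta[t, ]
    g <- g / sum(g)
    post_mean[t] <- sum(g * grid)
    post_var[t] <- sum(g * (grid - post_mean[t])^2)
  }
  list(years = series$years, mean = post_mean, var = post_var)
}
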