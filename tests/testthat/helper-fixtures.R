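# shared fixture builders; everything is generated in code at test time

small_config <- function(seed = 11, ...) {
  args <- list(n_neighbourhoods = 120, n_participants = 400,
               participant_neighbourhoods = 60, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(city_config, args)
}

# clustered binary data with a single z-scored exposure, for model tests:
# truth eta = intercept + beta * z(x) + u_j
make_clustered <- function(seed, n_groups = 40, per_group = 15,
                           intercept = qlogis(0.173), beta = 0.18,
                           sigma_u = 0.5) {
  set.seed(seed)
  g <- rep(seq_len(n_groups), each = per_group)
  xg <- rnorm(n_groups)
  x <- as.numeric(scale(xg[g]))
  u <- rnorm(n_groups, 0, sigma_u)
  y <- rbinom(length(g), 1, plogis(intercept + beta * x + u[g]))
  data.frame(non_daily = y, expo = x,
             neighbourhood_id = sprintf("N%03d", g),
             stringsAsFactors = FALSE)
}

# dense trapezoid integration of the marginal likelihood over the
# random intercept, independent of the quadrature path
bruteforce_loglik <- function(beta, sigma_u, y, X, group,
                              lim = 12, n_grid = 40001) {
  gl <- split(seq_along(y), group)
  uu <- seq(-lim, lim, length.out = n_grid)
  h <- uu[2] - uu[1]
  sum(vapply(gl, function(idx) {
    eta0 <- as.numeric(X[idx, , drop = FALSE] %*% beta)
    lg <- vapply(uu, function(v) {
      eta <- eta0 + v
      sum(y[idx] * eta - log1p(exp(eta))) + dnorm(v, 0, sigma_u, log = TRUE)
    }, numeric(1))
    m <- max(lg)
    m + log(sum(exp(lg - m)) * h)
  }, numeric(1)))
}
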