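# independent brute-force oracles, deliberately naive

# Efron partial log-likelihood for a single covariate
efronLoglik <- function(beta, time, status, x) {
  eta <- beta * x
  ll <- 0
  for (t in sort(unique(time[status == 1]))) {
    D <- which(time == t & status == 1)
    R <- which(time >= t)
    k <- length(D)
    sumR <- sum(exp(eta[R]))
    sumD <- sum(exp(eta[D]))
    ll <- ll + sum(eta[D])
    for (l in seq_len(k) - 1L)
      ll <- ll - log(sumR - (l / k) * sumD)
  }
  ll
}

# grid maximization of the Efron partial likelihood over beta in [-3, 3]
gridMaxCox <- function(time, status, x, step = 1e-4) {
  grid <- seq(-3, 3, by = step)
  ll <- vapply(grid, efronLoglik, 0, time = time, status = status, x = x)
  grid[which.max(ll)]
}

# draw survival data whose covariate effect changes over time
# (log HR b1 before tcut, b2 after) -- piecewise exponential
simTimeVarying <- function(n, x, h0, b1, b2, tcut, cmax) {
  r1 <- h0 * exp(b1 * x)
  r2 <- h0 * exp(b2 * x)
  t1 <- rexp(n) / r1
  t <- ifelse(t1 <= tcut, t1, tcut + rexp(n) / r2)
  cens <- runif(n, 0, cmax)
  data.frame(time = pmin(t, cens), status = as.integer(t <= cens))
}
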