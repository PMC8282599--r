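# Independent oracles used to validate the implementation paths.

# Brute-force Breslow partial log-likelihood for counting-process data with a
# single binary covariate, maximised by grid search. Kept independent of
# fit_cox_td (which delegates to survival::coxph).
breslow_grid_beta <- function(rows, grid = seq(-5, 5, by = 1e-4)) {
  ev <- rows[rows$event == 1, ]
  ll <- grid * sum(ev$x_threshold)
  for (t_j in unique(ev$t_stop)) {
    d_j <- sum(ev$t_stop == t_j)
    at_risk <- rows$t_start < t_j & rows$t_stop >= t_j
    n1 <- sum(rows$x_threshold[at_risk] == 1)
    n0 <- sum(at_risk) - n1
    ll <- ll - d_j * log(n0 + n1 * exp(grid))
  }
  grid[which.max(ll)]
}

# Independent central-thickness oracle for a phantom: 2-D Cartesian grid
# quadrature over the central disk, with the normal ray to the posterior
# sphere found by uniroot on the signed distance (no closed-form intersection,
# unlike the package's truth computation).
oracle_central_thickness <- function(truth, upper = "endm_anterior",
                                     diameter_um = 2000, n = 61) {
  f <- truth$interfaces[[upper]]
  fp <- truth$interfaces$posterior
  a <- diameter_um / 2
  g <- seq(-a, a, length.out = n)
  pts <- expand.grid(x = g, y = g)
  pts <- pts[pts$x^2 + pts$y^2 <= a^2, ]
  h <- 0.05
  vals <- vapply(seq_len(nrow(pts)), function(i) {
    x <- pts$x[i]; y <- pts$y[i]
    fx <- (f(x + h, y) - f(x - h, y)) / (2 * h)
    fy <- (f(x, y + h) - f(x, y - h)) / (2 * h)
    nrm <- sqrt(1 + fx^2 + fy^2)
    d <- c(-fx, -fy, 1) / nrm
    z0 <- f(x, y)
    gfun <- function(t) (z0 + t * d[3]) - fp(x + t * d[1], y + t * d[2])
    uniroot(gfun, c(0, 1500), tol = 1e-9)$root
  }, numeric(1))
  mean(vals)
}

# OLS polynomial fit in a prescribed normalised coordinate (oracle for RANSAC
# on known-clean subsets).
ols_poly <- function(u, y, degree) {
  qr.coef(qr(outer(u, 0:degree, `^`)), y)
}
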