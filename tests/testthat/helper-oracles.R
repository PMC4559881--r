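# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: fine-grid quadrature for AUC, a fixed-step RK4
# integrator for the turnover ODE, and brute-force/grid scans.

# fine-grid trapezoid of the piecewise-linear interpolant of (t, c)
oracle_auc_finegrid <- function(times, conc, t_start, t_end, dt = 1e-3) {
  g <- seq(t_start, t_end, by = dt)
  if (g[length(g)] < t_end) g <- c(g, t_end)
  y <- approx(times, conc, xout = g)$y
  sum(diff(g) * (head(y, -1) + tail(y, -1)) / 2)
}

# classic fixed-step RK4 for dR/dt = kin*(1 - imax*C(t)/(ic50+C(t))) - kout*R
oracle_rk4_turnover <- function(kin, kout, ic50, imax, cfun, r0, t_end,
                                dt = 1e-3) {
  f <- function(t, r) {
    ct <- cfun(t)
    kin * (1 - imax * ct / (ic50 + ct)) - kout * r
  }
  n <- ceiling(t_end / dt)
  r <- r0
  t <- 0
  out_t <- numeric(n + 1L); out_r <- numeric(n + 1L)
  out_t[1L] <- 0; out_r[1L] <- r0
  for (i in seq_len(n)) {
    h <- min(dt, t_end - t)
    k1 <- f(t, r)
    k2 <- f(t + h / 2, r + h / 2 * k1)
    k3 <- f(t + h / 2, r + h / 2 * k2)
    k4 <- f(t + h, r + h * k3)
    r <- r + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + h
    out_t[i + 1L] <- t; out_r[i + 1L] <- r
  }
  list(time = out_t, response = out_r)
}

# a reproducible "random" profile for scan-type oracles
random_profile <- function(n = 200, seed = 42) {
  set.seed(seed)
  times <- sort(runif(n, 0, 48))
  times <- times + seq_along(times) * 1e-6   # enforce strict increase
  conc <- rlnorm(n, meanlog = 0, sdlog = 1)
  ct_profile(times = times, conc = conc, matrix = "blood")
}

# closed-form one-compartment oral curve as a function of time (mirrors the
# model definition, written out independently of the package internals)
oral_conc_fun <- function(fo) {
  function(t) {
    tt <- pmax(t - fo$lag, 0)
    fo$dose_scaled * fo$ka / (fo$ka - fo$ke) *
      (exp(-fo$ke * tt) - exp(-fo$ka * tt))
  }
}

# textbook Pearson r^2 via the covariance formula, no stats::cor
oracle_r2 <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  (sxy / (sd(x) * sd(y)))^2
}
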