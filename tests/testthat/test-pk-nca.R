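test_that("cmax_tmax finds the observed peak, with earliest-time tie-breaking", {
  p <- ct_profile(times = c(1, 2, 4), conc = c(1.62, 1.1, 0.6),
                  matrix = "blood")
  expect_equal(cmax_tmax(p), list(cmax = 1.62, tmax = 1))

  # monotone decreasing profile: first point is the peak
  mono <- ct_profile(times = 1:6, conc = 10 * exp(-0.5 * (1:6)))
  expect_equal(cmax_tmax(mono)$tmax, 1)

  # exact tie: earliest time wins
  tie <- ct_profile(times = c(1, 2, 3), conc = c(5, 5, 1))
  expect_equal(cmax_tmax(tie)$tmax, 1)

  # 200-point profile equals an exhaustive scan
  rp <- random_profile(200)
  best <- list(cmax = -Inf, tmax = NA)
  for (i in seq_along(rp$times))
    if (rp$conc[i] > best$cmax) best <- list(cmax = rp$conc[i], tmax = rp$times[i])
  expect_equal(cmax_tmax(rp), best)
})

test_that("cmax_tmax rejects profiles with no quantifiable sample", {
  blq <- ct_profile(times = c(1, 2), conc = c(NA, NA), blq = c(TRUE, TRUE),
                    lloq = 0.1)
  expect_error(cmax_tmax(blq), "no quantifiable")
})

test_that("trapezoidal AUC: rectangle, fine-grid oracle, additivity", {
  const <- ct_profile(times = c(0, 6, 12, 24), conc = rep(1, 4))
  expect_equal(auc_trapezoid(const, 0, 24), 24)

  # piecewise-linear profile vs fine-grid quadrature
  p <- ct_profile(times = c(0, 1, 2.5, 4, 8, 12, 24),
                  conc = c(0, 3.2, 2.8, 1.9, 0.8, 0.3, 0.05))
  expect_equal(auc_trapezoid(p, 0, 24),
               oracle_auc_finegrid(p$times, p$conc, 0, 24),
               tolerance = 1e-6)

  # additivity over an interior grid point, and over a non-grid split
  rp <- random_profile(50, seed = 7)
  t0 <- rp$times[1]; t1 <- rp$times[25]; t2 <- rp$times[50]
  expect_equal(auc_trapezoid(rp, t0, t1) + auc_trapezoid(rp, t1, t2),
               auc_trapezoid(rp, t0, t2), tolerance = 1e-12)
  tm <- (t0 + t2) / 2
  expect_equal(auc_trapezoid(rp, t0, tm) + auc_trapezoid(rp, tm, t2),
               auc_trapezoid(rp, t0, t2), tolerance = 1e-12)
})

test_that("AUC window outside the observed range is an error naming the gap", {
  p <- ct_profile(times = c(1, 2, 4), conc = c(1, 2, 1))
  expect_error(auc_trapezoid(p, 0, 4), "outside the observed range")
  expect_error(auc_trapezoid(p, 1, 8), "outside the observed range")
})

test_that("BLQ samples: zero before first quantifiable, LLOQ/2 after", {
  p <- ct_profile(times = c(0, 1, 2, 4, 8),
                  conc = c(NA, 4, 2, NA, NA),
                  blq = c(TRUE, FALSE, FALSE, TRUE, TRUE),
                  lloq = 0.2)
  # hand trapezoid: (0+4)/2*1 + (4+2)/2*1 + (2+0.1)/2*2 + (0.1+0.1)/2*4
  expect_equal(auc_trapezoid(p, 0, 8), 2 + 3 + 2.1 + 0.4)
})

test_that("terminal half-life: closed form, noiseless recovery, noisy bound", {
  tt <- c(0.5, 1, 2, 4, 8, 12, 24)
  p <- ct_profile(times = tt, conc = 10 * exp(-0.1 * tt))
  th <- terminal_half_life(p)
  expect_equal(th$t_half, log(2) / 0.1, tolerance = 1e-6)
  expect_equal(th$t_half * th$lambda_z, log(2))   # exact invariant

  for (ke in c(0.05, 0.3, 1.2)) {
    pe <- ct_profile(times = tt, conc = 5 * exp(-ke * tt))
    expect_equal(terminal_half_life(pe)$lambda_z, ke, tolerance = 1e-8)
  }

  # 10 % lognormal noise, fixed seed: within 15 % of truth
  set.seed(11)
  noisy <- 5 * exp(-0.25 * tt) * exp(rnorm(length(tt), 0, sqrt(log(1.01))))
  pn <- ct_profile(times = tt, conc = noisy)
  expect_lt(abs(terminal_half_life(pn)$lambda_z - 0.25) / 0.25, 0.15)
})

test_that("terminal half-life rejects profiles without a decline", {
  rising <- ct_profile(times = c(1, 2, 4, 8, 16), conc = c(1, 2, 3, 4, 5))
  expect_error(terminal_half_life(rising), "at least 3 samples after Tmax")
  flat <- ct_profile(times = c(0.5, 1, 2, 4, 8), conc = c(5, 1, 1, 1, 1))
  expect_error(terminal_half_life(flat), "no measurable terminal decline")
})

test_that("nca_summary recovers one-compartment truth and bioavailability", {
  iv <- gen_pk_profile("rat", route = "iv")
  po <- gen_pk_profile("rat", route = "po")
  r <- nca_summary(iv$profile, po$profile)
  p <- pk_preset("rat")
  expect_equal(r$clearance, p$cl_ml_min_kg, tolerance = 0.02)
  expect_equal(r$vz, p$v_l_kg, tolerance = 0.02)
  expect_equal(r$f_oral, p$f_oral, tolerance = 0.02)
  expect_equal(r$t_half, p$t_half_h, tolerance = 1e-6)

  # identical dose-normalized AUCs: F = 100 %
  tt <- c(0.25, 0.5, 1, 2, 4, 8, 12, 24)
  base <- 4 * exp(-0.3 * tt)
  a <- ct_profile(times = tt, conc = base, dose = 2, route = "iv")
  b <- ct_profile(times = tt, conc = 3 * base, dose = 6, route = "po")
  expect_equal(nca_summary(a, b)$f_oral, 1, tolerance = 1e-10)

  # halved dose-normalized oral AUC: F = 50 %
  h <- ct_profile(times = tt, conc = 1.5 * base, dose = 6, route = "po")
  expect_equal(nca_summary(a, h)$f_oral, 0.5, tolerance = 1e-10)
})

test_that("nca_summary flags > 20 % AUC extrapolation", {
  tt <- c(0.25, 0.5, 1, 2, 3, 4)        # truncated well before 5 half-lives
  iv <- ct_profile(times = tt, conc = 4 * exp(-0.15 * tt), dose = 2,
                   route = "iv")
  po <- ct_profile(times = tt, conc = 2 * exp(-0.15 * tt), dose = 6,
                   route = "po")
  r <- nca_summary(iv, po)
  expect_true(any(grepl("exceeds 20 %", r$warnings)))
})

test_that("unbound exposure arithmetic matches the printed free AUCs", {
  expect_equal(round(unbound_auc(10.2, binding_params(93.8)), 2), 0.63)
  expect_equal(round(unbound_auc(23.6, binding_params(97.7, "brain_homogenate")), 2),
               0.54)
  expect_equal(unbound_auc(7.3, binding_params(0)), 7.3)   # identity at 0 %

  # strictly decreasing in bound percent
  fr <- vapply(c(0, 20, 50, 90, 99), function(b) unbound_auc(1, binding_params(b)),
               numeric(1))
  expect_true(all(diff(fr) < 0))
  expect_error(binding_params(100), "fu would be undefined")
})

test_that("efflux ratio arithmetic and guards", {
  expect_equal(round(efflux_ratio(26.3e-6, 14.1e-6), 1), 1.9)
  expect_equal(efflux_ratio(5, 5), 1)
  expect_equal(efflux_ratio(14.1e-6, 26.3e-6), 1 / efflux_ratio(26.3e-6, 14.1e-6))
  expect_error(efflux_ratio(0, 1), "positive")
  expect_error(efflux_ratio(1, -2), "positive")
})

test_that("profile CSV reader round-trips generated data", {
  g <- gen_pk_profile("rat", route = "po", noise_cv = 0.1, seed = 4)
  df <- as.data.frame(g$profile)
  f <- tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  back <- read_profiles(f)
  expect_length(back, 1)
  expect_equal(back[[1]]$conc, g$profile$conc)
  expect_equal(back[[1]]$times, g$profile$times)
  expect_error(read_profiles({
    f2 <- tempfile(fileext = ".csv")
    write.csv(df[, -3], f2, row.names = FALSE); f2
  }), "missing required column")
  unlink(f)
})
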