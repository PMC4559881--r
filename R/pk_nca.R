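#' @title Non-compartmental PK analysis
#' @description Model-free summaries of concentration-time profiles: Cmax,
#'   trapezoidal AUC, terminal half-life, clearance, volume of distribution
#'   and oral bioavailability, plus the binding/transport arithmetic used to
#'   scale total to unbound exposure. All functions keep full precision;
#'   rounding to reporting precision is the caller's concern.
#' @name pk_nca
NULL

#' Maximum observed concentration and its time
#'
#' Scans the quantifiable post-dose samples of a profile for the maximum
#' observed concentration. Ties are broken in favour of the earliest time.
#'
#' @param profile A [ct_profile].
#' @return List with elements `cmax` and `tmax` (hours).
#' @export
cmax_tmax <- function(profile) {
  stopifnot(inherits(profile, "ct_profile"))
  q <- quantifiable(profile, postdose_only = TRUE)
  if (length(q$times) == 0L)
    stop("no quantifiable concentration: all post-dose samples are BLQ or absent")
  i <- which.max(q$conc)  # which.max returns the first (earliest) maximum
  list(cmax = q$conc[i], tmax = q$times[i])
}

# impute BLQ samples for AUC: 0 before the first quantifiable sample,
# LLOQ/2 embedded or after (standard NCA convention)
auc_working_conc <- function(profile) {
  conc <- profile$conc
  if (any(profile$blq)) {
    qt <- profile$times[!profile$blq]
    if (length(qt) == 0L)
      stop("no quantifiable concentration: all samples are BLQ")
    first_q <- min(qt)
    half <- if (is.na(profile$lloq)) 0 else profile$lloq / 2
    conc[profile$blq] <- ifelse(profile$times[profile$blq] < first_q, 0, half)
  }
  conc
}

#' Linear-trapezoidal area under the curve
#'
#' Area under the concentration-time curve over `[t_start, t_end]` by the
#' linear trapezoidal rule on the observed sampling grid. Window endpoints
#' that fall between samples are handled by linear interpolation, which
#' keeps the result exactly additive over adjacent windows. BLQ samples
#' before the first quantifiable point contribute 0; embedded or trailing
#' BLQ samples contribute LLOQ/2.
#'
#' @param profile A [ct_profile].
#' @param t_start,t_end Window bounds in hours; default to the full
#'   observed range.
#' @return AUC in concentration x hours.
#' @export
auc_trapezoid <- function(profile, t_start = NULL, t_end = NULL) {
  stopifnot(inherits(profile, "ct_profile"))
  conc <- auc_working_conc(profile)
  times <- profile$times
  if (is.null(t_start)) t_start <- times[1L]
  if (is.null(t_end)) t_end <- times[length(times)]
  if (t_end <= t_start) stop("`t_end` must exceed `t_start`")
  if (t_start < times[1L] || t_end > times[length(times)])
    stop(sprintf(
      "window [%g, %g] h extends outside the observed range [%g, %g] h",
      t_start, t_end, times[1L], times[length(times)]))
  inside <- times >= t_start & times <= t_end
  if (sum(inside) < 2L)
    stop("fewer than 2 samples inside the AUC window")
  tt <- sort(unique(c(t_start, times[inside], t_end)))
  cc <- stats::approx(times, conc, xout = tt, rule = 1)$y
  sum(diff(tt) * (utils::head(cc, -1) + utils::tail(cc, -1)) / 2)
}

#' Terminal elimination rate and half-life
#'
#' Log-linear least-squares regression on the terminal phase. The terminal
#' points are the last three quantifiable samples after Tmax by default; the
#' window is extended one earlier sample at a time for as long as the
#' adjusted R-squared of the regression improves.
#'
#' @param profile A [ct_profile].
#' @param n_points Override the automatic selection with a fixed number of
#'   terminal points (counted from the last sample backwards, all after
#'   Tmax).
#' @return List with `lambda_z` (1/h), `t_half` (h), `n_points`, `adj_r2`,
#'   `intercept` (log scale) and `clast_pred` (regression-predicted
#'   concentration at the last quantifiable time, used for AUC
#'   extrapolation).
#' @export
terminal_half_life <- function(profile, n_points = NULL) {
  stopifnot(inherits(profile, "ct_profile"))
  q <- quantifiable(profile, postdose_only = TRUE)
  keep <- q$conc > 0
  tt <- q$times[keep]; cc <- q$conc[keep]
  if (length(tt) < 3L) stop("need at least 3 positive post-dose samples")
  tmax <- tt[which.max(cc)]
  term_t <- tt[tt > tmax]; term_c <- cc[tt > tmax]
  n_avail <- length(term_t)
  if (n_avail < 3L)
    stop("need at least 3 samples after Tmax for the terminal regression")
  fit_n <- function(n) {
    i <- seq.int(n_avail - n + 1L, n_avail)
    f <- stats::lm(log(term_c[i]) ~ term_t[i])
    list(n = n, slope = stats::coef(f)[[2L]], intercept = stats::coef(f)[[1L]],
         adj_r2 = suppressWarnings(summary(f)$adj.r.squared))
  }
  if (!is.null(n_points)) {
    if (n_points < 3L || n_points > n_avail)
      stop("`n_points` must be between 3 and the number of post-Tmax samples")
    best <- fit_n(n_points)
  } else {
    best <- fit_n(3L)
    n <- 3L
    while (n < n_avail) {
      cand <- fit_n(n + 1L)
      if (is.na(cand$adj_r2) || is.na(best$adj_r2) ||
          cand$adj_r2 <= best$adj_r2) break
      best <- cand
      n <- n + 1L
    }
  }
  if (best$slope >= 0)
    stop("no measurable terminal decline (non-negative terminal slope)")
  lambda_z <- -best$slope
  list(lambda_z = lambda_z, t_half = log(2) / lambda_z,
       n_points = best$n, adj_r2 = best$adj_r2,
       intercept = best$intercept,
       clast_pred = exp(best$intercept + best$slope * tt[length(tt)]),
       tlast = tt[length(tt)])
}

#' Non-compartmental PK summary from a matched iv/po pair
#'
#' Computes the standard NCA quantities for a compound dosed both
#' intravenously and orally in the same species: Cmax/Tmax (oral), AUC to
#' the last sample and extrapolated to infinity, terminal rate and
#' half-life, clearance, terminal volume of distribution and absolute oral
#' bioavailability. Doses are in umol/kg and concentrations in uM, so
#' AUC-based clearance comes out in l/h/kg and is converted to the
#' conventional ml/min/kg.
#'
#' Extrapolation to infinity uses the regression-predicted last
#' concentration, `AUC_inf = AUC_0_t + Clast_pred / lambda_z`. If the
#' extrapolated fraction of either AUC exceeds 20 % a warning is recorded
#' in the result's `warnings` field.
#'
#' @param iv_profile,po_profile Matched [ct_profile] objects with doses.
#' @return An object of class `nca_result`: `cmax`, `tmax`, `auc_0_t`,
#'   `auc_0_inf` (both routes), `lambda_z`, `t_half`, `clearance`
#'   (ml/min/kg), `vz` (l/kg), `f_oral` (fraction), `warnings`.
#' @export
nca_summary <- function(iv_profile, po_profile) {
  stopifnot(inherits(iv_profile, "ct_profile"),
            inherits(po_profile, "ct_profile"))
  if (is.na(iv_profile$dose) || is.na(po_profile$dose) ||
      iv_profile$dose <= 0 || po_profile$dose <= 0)
    stop("both profiles need positive doses")
  warnings <- character()
  summarise_route <- function(p) {
    term <- terminal_half_life(p)
    auc_t <- auc_trapezoid(p, max(0, p$times[1L]), p$times[length(p$times)])
    auc_inf <- auc_t + term$clast_pred / term$lambda_z
    extrap <- 1 - auc_t / auc_inf
    list(term = term, auc_t = auc_t, auc_inf = auc_inf, extrap = extrap)
  }
  iv <- summarise_route(iv_profile)
  po <- summarise_route(po_profile)
  for (r in list(c("iv", iv$extrap), c("po", po$extrap)))
    if (as.numeric(r[2L]) > 0.20)
      warnings <- c(warnings, sprintf(
        "%s AUC extrapolated fraction %.1f %% exceeds 20 %%",
        r[1L], 100 * as.numeric(r[2L])))
  peak <- cmax_tmax(po_profile)
  cl_l_h_kg <- iv_profile$dose / iv$auc_inf     # (umol/kg)/(uM*h) = l/h/kg
  f <- (po$auc_inf / po_profile$dose) / (iv$auc_inf / iv_profile$dose)
  if (f > 1.05)
    warnings <- c(warnings, sprintf("F = %.2f exceeds 1.05", f))
  structure(
    list(cmax = peak$cmax, tmax = peak$tmax,
         auc_0_t = c(iv = iv$auc_t, po = po$auc_t),
         auc_0_inf = c(iv = iv$auc_inf, po = po$auc_inf),
         lambda_z = iv$term$lambda_z,
         t_half = iv$term$t_half,
         clearance = cl_l_h_kg * 1000 / 60,     # ml/min/kg
         vz = cl_l_h_kg / iv$term$lambda_z,     # l/kg
         f_oral = f,
         extrap_fraction = c(iv = iv$extrap, po = po$extrap),
         warnings = warnings),
    class = "nca_result")
}

#' @export
print.nca_result <- function(x, ...) {
  cat("<nca_result>\n")
  cat(sprintf("  Cmax %.3g at %g h (po)\n", x$cmax, x$tmax))
  cat(sprintf("  AUCinf iv %.4g, po %.4g conc*h\n",
              x$auc_0_inf[["iv"]], x$auc_0_inf[["po"]]))
  cat(sprintf("  CL %.3g ml/min/kg, t1/2 %.3g h, Vz %.3g l/kg, F %.1f %%\n",
              x$clearance, x$t_half, x$vz, 100 * x$f_oral))
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}

#' Unbound (free) exposure from total exposure and binding
#'
#' Multiplies a total AUC by the free fraction `fu = 1 - bound/100`,
#' converting total to unbound exposure. With a rat plasma binding of
#' 93.8 % a blood AUC of 10.2 uM*h gives an unbound AUC of 0.63 uM*h; with
#' a brain homogenate binding of 97.7 %, a brain AUC of 23.6 uM*h gives
#' 0.54 uM*h.
#'
#' @param auc_total Total AUC (conc x h), `>= 0`.
#' @param binding A [binding_params] object, or a bound percentage.
#' @return Unbound AUC, same units, full precision.
#' @export
unbound_auc <- function(auc_total, binding) {
  if (!inherits(binding, "binding_params")) binding <- binding_params(binding)
  if (!is.finite(auc_total) || auc_total < 0) stop("`auc_total` must be >= 0")
  auc_total * binding$fu
}

#' Efflux ratio from bidirectional transporter-monolayer fluxes
#'
#' Ratio of basolateral-to-apical over apical-to-basolateral permeability
#' in a transporter-expressing cell monolayer (e.g. MDR1-MDCK). Ratios
#' well above ~2 indicate transporter-limited permeation.
#'
#' @param flux_ba,flux_ab Permeabilities (cm/s), both `> 0`.
#' @return `flux_ba / flux_ab`.
#' @export
efflux_ratio <- function(flux_ba, flux_ab) {
  if (!is.finite(flux_ba) || flux_ba <= 0 ||
      !is.finite(flux_ab) || flux_ab <= 0)
    stop("both fluxes must be positive")
  flux_ba / flux_ab
}
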