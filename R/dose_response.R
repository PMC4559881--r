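#' @title Dose-response analysis
#' @description Percent-inhibition normalization and four-parameter
#'   logistic (4PL) fitting, the standard sigmoid used for in vitro IC50
#'   and in vivo ED50 estimation.
#' @name dose_response
NULL

#' Percent inhibition relative to a reference (vehicle) mean
#'
#' `100 * (1 - treated/reference)`. Negative values indicate an increase
#' over the reference. Vectorized over `treated_mean`.
#'
#' @param treated_mean Analyte level(s) under treatment.
#' @param reference_mean Vehicle/reference analyte level, `> 0`.
#' @return Percent inhibition.
#' @export
percent_inhibition <- function(treated_mean, reference_mean) {
  if (!is.finite(reference_mean) || reference_mean <= 0)
    stop("`reference_mean` must be positive")
  100 * (1 - treated_mean / reference_mean)
}

# 4PL curve: y = bottom + (top - bottom) / (1 + (x/midpoint)^hill).
# With hill > 0 the curve falls from `top` (x << midpoint) to `bottom`;
# an increasing response carries a negative hill.
curve_4pl <- function(x, bottom, top, midpoint, hill) {
  bottom + (top - bottom) / (1 + (x / midpoint)^hill)
}

#' Four-parameter logistic fit
#'
#' Least-squares fit of `y = bottom + (top - bottom)/(1 + (x/midpoint)^hill)`
#' with the midpoint parameterized as `log10(midpoint)`, so the fit is
#' carried out on the log-dose axis and the midpoint stays positive.
#' Standard errors are asymptotic (Jacobian-based); the midpoint SE is
#' transported back from the log scale by the delta method, matching the
#' conventional "estimate +/- SE" reporting of potency values.
#'
#' Starting values: `top = max(y)`, `bottom = min(y)`, midpoint at the dose
#' whose response is nearest to the half-range, `|hill| = 1` with the sign
#' taken from the observed direction of the response.
#'
#' @param x Doses or concentrations, `> 0`, at least 4 distinct values.
#' @param y Responses, same length.
#' @param fix_bottom,fix_top Optionally freeze an asymptote (e.g.
#'   `fix_bottom = 0` for inhibition data on the percent scale).
#' @return A `dr_fit` object: `bottom`, `top`, `midpoint`, `hill`,
#'   `se_midpoint`, `se` (all parameters), `rss`, `fitted`, `converged`,
#'   `niter`.
#' @export
fit_4pl <- function(x, y, fix_bottom = NULL, fix_top = NULL) {
  stopifnot(length(x) == length(y))
  if (any(x <= 0)) stop("doses/concentrations must be positive (vehicle enters only through normalization)")
  if (length(unique(x)) < 4L) stop("need at least 4 distinct x values")
  lx <- log10(x)
  direction <- sign(stats::cor(lx, y))
  if (!is.finite(direction) || direction == 0) direction <- -1
  top0 <- if (is.null(fix_top)) max(y) else fix_top
  bot0 <- if (is.null(fix_bottom)) min(y) else fix_bottom
  half <- (top0 + bot0) / 2
  mid0 <- x[which.min(abs(y - half))]
  par0 <- c(lmid = log10(mid0), hill = -direction)
  lower <- c(lmid = min(lx) - 3, hill = -50)
  upper <- c(lmid = max(lx) + 3, hill = 50)
  if (is.null(fix_bottom)) {
    par0 <- c(par0, bottom = bot0)
    lower <- c(lower, bottom = -Inf); upper <- c(upper, bottom = Inf)
  }
  if (is.null(fix_top)) {
    par0 <- c(par0, top = top0)
    lower <- c(lower, top = -Inf); upper <- c(upper, top = Inf)
  }
  model <- function(p) {
    bottom <- if (is.null(fix_bottom)) p[["bottom"]] else fix_bottom
    top <- if (is.null(fix_top)) p[["top"]] else fix_top
    bottom + (top - bottom) / (1 + 10^((lx - p[["lmid"]]) * p[["hill"]]))
  }
  fit <- minpack.lm::nls.lm(
    par = par0, fn = function(p) y - model(p),
    lower = lower[names(par0)], upper = upper[names(par0)],
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-13))
  if (fit$info < 1 || fit$info > 4)
    stop(structure(class = c("fit_4pl_error", "error", "condition"),
                   list(message = paste0("4PL fit failed to converge: ",
                                         fit$message),
                        call = sys.call(-1), par = fit$par)))
  cf <- fit$par
  dof <- max(length(y) - length(cf), 1L)
  s2 <- fit$deviance / dof
  covm <- tryCatch(solve(fit$hessian) * s2, error = function(e) NULL)
  se <- if (!is.null(covm) && all(diag(covm) >= 0)) sqrt(diag(covm)) else
    stats::setNames(rep(NA_real_, length(cf)), names(cf))
  midpoint <- 10^cf[["lmid"]]
  se_mid <- log(10) * midpoint * se[["lmid"]]
  bottom <- if (is.null(fix_bottom)) cf[["bottom"]] else fix_bottom
  top <- if (is.null(fix_top)) cf[["top"]] else fix_top
  structure(
    list(bottom = bottom, top = top, midpoint = midpoint,
         hill = cf[["hill"]], se_midpoint = se_mid, se = se,
         rss = fit$deviance,
         fitted = model(cf),
         converged = TRUE, niter = fit$niter,
         unidentifiable = FALSE),
    class = "dr_fit")
}

#' @export
print.dr_fit <- function(x, ...) {
  cat(sprintf(
    "<dr_fit> midpoint %.4g +/- %.2g, hill %.3g, bottom %.3g, top %.3g (RSS %.4g)\n",
    x$midpoint, x$se_midpoint, x$hill, x$bottom, x$top, x$rss))
  if (x$unidentifiable) cat("  flag: midpoint unidentifiable for this design\n")
  invisible(x)
}

#' Predict from a 4PL fit
#' @param object A `dr_fit`.
#' @param newdata Doses at which to evaluate the fitted curve.
#' @param ... Unused.
#' @export
predict.dr_fit <- function(object, newdata, ...) {
  curve_4pl(newdata, object$bottom, object$top, object$midpoint, object$hill)
}

#' In vivo ED50 from a dose-ranging study
#'
#' Converts treated group means to percent inhibition of the vehicle mean
#' and fits a 4PL with the bottom asymptote fixed at 0 (no drug, no
#' inhibition). The vehicle group enters only through the normalization; it
#' is never a fitted point, so `log(0)` never arises.
#'
#' @param dose_groups Named numeric vector of treated group means; names
#'   are the doses (umol/kg). At least 4 dose groups are required.
#' @param vehicle_mean Vehicle group mean, `> 0`.
#' @return A `dr_fit` whose `midpoint` is the ED50 on the dose scale, with
#'   `inhibition` (the normalized responses) attached. If the design shows
#'   no dose-related response the fit is rejected with a `"no response"`
#'   error; if the response is saturated at every dose the returned fit
#'   carries `unidentifiable = TRUE` and a warning.
#' @export
ed50_from_study <- function(dose_groups, vehicle_mean) {
  doses <- as.numeric(names(dose_groups))
  if (any(is.na(doses))) stop("`dose_groups` must be named by numeric doses")
  if (length(doses) < 4L) stop("need at least 4 dose groups")
  inh <- percent_inhibition(as.numeric(dose_groups), vehicle_mean)
  if (max(abs(inh)) < 5)
    stop("no response: all dose groups are within 5 % of vehicle")
  fit <- fit_4pl(doses, inh, fix_bottom = 0)
  fit$inhibition <- stats::setNames(inh, names(dose_groups))
  # a midpoint below the lowest or above the highest dose is extrapolation:
  # every observed dose sits on the same side of the half-maximum
  if (fit$midpoint < min(doses) || fit$midpoint > max(doses)) {
    fit$unidentifiable <- TRUE
    warning("ED50 falls outside the tested dose range; midpoint unidentifiable")
  }
  fit
}
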