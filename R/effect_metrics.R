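#' @title Effect normalization and summary metrics
#' @description Percent-of-predose and percent-of-vehicle normalization,
#'   time-averaged area under the effect curve (AUEC) over a dosing
#'   interval, and signed group percent-change summaries.
#' @name effect_metrics
NULL

#' Effect (biomarker) time series
#'
#' @param times Sampling times (h); negative times denote predose samples.
#' @param values Analyte levels (or percents after normalization), `>= 0`.
#' @param normalization One of `"raw"`, `"pct_predose"`, `"pct_vehicle"`,
#'   `"pct_reduction"`.
#' @return An `effect_series` object.
#' @export
effect_series <- function(times, values,
                          normalization = c("raw", "pct_predose",
                                            "pct_vehicle", "pct_reduction")) {
  normalization <- match.arg(normalization)
  times <- as.numeric(times); values <- as.numeric(values)
  stopifnot(length(times) == length(values))
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing")
  if (any(values < 0)) stop("negative analyte values")
  structure(list(times = times, values = values,
                 normalization = normalization),
            class = "effect_series")
}

#' @export
print.effect_series <- function(x, ...) {
  cat(sprintf("<effect_series> %d points, %g-%g h, normalization: %s\n",
              length(x$times), min(x$times), max(x$times), x$normalization))
  invisible(x)
}

#' Normalize a series to the mean of its predose samples
#'
#' Each value becomes `100 * value / mean(predose values)` — the standard
#' "percent of predose baseline" scale for serial-sampling studies with
#' predose draws (e.g. at -24 h and -1 h). The predose mean is kept as an
#' attribute so the transformation can be inverted exactly with
#' [denormalize_predose()].
#'
#' @param series An [effect_series] with `normalization == "raw"`.
#' @param predose_times Times (h) of the predose samples; every one must
#'   be present in the series.
#' @return The normalized [effect_series] (`normalization = "pct_predose"`).
#' @export
normalize_to_predose <- function(series, predose_times = c(-24, -1)) {
  stopifnot(inherits(series, "effect_series"))
  idx <- match(predose_times, series$times)
  if (anyNA(idx))
    stop("predose sample missing at t = ",
         paste(predose_times[is.na(idx)], collapse = ", "), " h")
  base <- mean(series$values[idx])
  if (base <= 0) stop("predose mean must be positive")
  out <- effect_series(series$times, 100 * series$values / base,
                       normalization = "pct_predose")
  attr(out, "predose_mean") <- base
  out
}

#' Invert a predose normalization
#' @param series An [effect_series] produced by [normalize_to_predose()].
#' @return The raw-scale [effect_series].
#' @export
denormalize_predose <- function(series) {
  base <- attr(series, "predose_mean")
  if (is.null(base)) stop("series carries no predose_mean attribute")
  effect_series(series$times, series$values * base / 100, "raw")
}

#' Time-averaged area under the effect curve
#'
#' Linear-trapezoid area of percent reduction versus time over a dosing
#' window, divided by the window length: the average percent reduction
#' sustained over the interval. From steady-state points
#' (0 h, 60 %), (4 h, 90 %), (24 h, 60 %) this gives 75 %.
#'
#' @param timepoints Times (h) at which reductions were measured.
#' @param reductions Percent reductions at those times.
#' @param window Two-element numeric, the averaging interval (h); both
#'   endpoints must be covered by `timepoints`.
#' @return Time-averaged percent reduction over the window.
#' @export
auec_reduction <- function(timepoints, reductions, window = c(0, 24)) {
  stopifnot(length(timepoints) == length(reductions), length(window) == 2L)
  o <- order(timepoints)
  tt <- timepoints[o]; rr <- reductions[o]
  if (window[1L] < tt[1L] || window[2L] > tt[length(tt)])
    stop(sprintf("window [%g, %g] h not covered by the observed times",
                 window[1L], window[2L]))
  inside <- tt >= window[1L] & tt <= window[2L]
  if (sum(inside) < 2L) stop("need at least 2 points inside the window")
  gx <- sort(unique(c(window, tt[inside])))
  gy <- stats::approx(tt, rr, xout = gx)$y
  area <- sum(diff(gx) * (utils::head(gy, -1) + utils::tail(gy, -1)) / 2)
  area / diff(window)
}

#' Signed percent change of a group mean versus a reference mean
#'
#' `100 * (group - reference)/reference`; negative values are reductions.
#' Satisfies `group_percent_change(a, b) == -percent_inhibition(a, b)`.
#'
#' @param group_mean Treated group mean.
#' @param reference_mean Reference (vehicle or baseline) mean, `> 0`.
#' @return Signed percent change; vectorized over `group_mean`.
#' @export
group_percent_change <- function(group_mean, reference_mean) {
  if (!is.finite(reference_mean) || reference_mean <= 0)
    stop("`reference_mean` must be positive")
  100 * (group_mean - reference_mean) / reference_mean
}
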