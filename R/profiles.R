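#' Concentration-time profile
#'
#' Container for one subject/matrix concentration-time series, the unit of
#' input for all non-compartmental analysis (NCA) functions. Concentrations
#' below the lower limit of quantification (LLOQ) are flagged `blq` rather
#' than stored as imputed numbers; imputation rules live in the consumers
#' (see [auc_trapezoid()]).
#'
#' @param times Numeric vector of sampling times in hours, strictly
#'   increasing. Negative times are allowed and denote predose samples.
#' @param conc Numeric vector of concentrations (same length as `times`),
#'   `NA` where the sample was below the LLOQ. Units are carried in `unit`
#'   and must be uniform within a profile.
#' @param blq Logical vector marking below-LLOQ samples. Defaults to
#'   `is.na(conc)`. A sample cannot be both numeric and BLQ.
#' @param subject_id Identifier of the animal/subject.
#' @param matrix One of `"blood"`, `"brain"`, `"csf"`, `"plasma"`.
#' @param unit Concentration unit label (e.g. `"uM"`, `"pg/ml"`).
#' @param lloq Lower limit of quantification, same unit, `> 0`.
#' @param dose Administered dose in umol/kg (`>= 0`; 0 for vehicle).
#' @param route `"po"` or `"iv"`.
#'
#' @return An object of class `ct_profile`.
#' @examples
#' p <- ct_profile(times = c(1, 2, 4, 8, 24),
#'                 conc  = c(1.62, 1.1, 0.6, 0.25, 0.04),
#'                 subject_id = "rat1", matrix = "blood",
#'                 unit = "uM", lloq = 0.01, dose = 30, route = "po")
#' cmax_tmax(p)
#' @export
ct_profile <- function(times, conc, blq = is.na(conc),
                       subject_id = "s1",
                       matrix = c("blood", "brain", "csf", "plasma"),
                       unit = "uM", lloq = NA_real_,
                       dose = NA_real_, route = c("po", "iv")) {
  matrix <- match.arg(matrix)
  route <- match.arg(route)
  times <- as.numeric(times)
  conc <- as.numeric(conc)
  blq <- as.logical(blq)
  if (length(conc) != length(times) || length(blq) != length(times))
    stop("`times`, `conc` and `blq` must have equal length")
  if (length(times) == 0L) stop("empty profile")
  if (any(!is.finite(times))) stop("non-finite times")
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing")
  if (any(blq & !is.na(conc) & conc > 0))
    stop("a sample cannot be both numeric (> 0) and flagged BLQ")
  if (any(!blq & is.na(conc)))
    stop("non-BLQ samples must carry a numeric concentration")
  if (any(conc[!blq] < 0)) stop("negative concentration")
  if (!is.na(lloq) && lloq <= 0) stop("`lloq` must be > 0")
  if (!is.na(dose) && dose < 0) stop("`dose` must be >= 0")
  structure(
    list(subject_id = subject_id, matrix = matrix,
         times = times, conc = conc, blq = blq,
         unit = unit, lloq = lloq, dose = dose, route = route),
    class = "ct_profile")
}

#' @export
print.ct_profile <- function(x, ...) {
  cat(sprintf("<ct_profile> %s/%s: %d samples, %g-%g h, dose %s umol/kg %s\n",
              x$subject_id, x$matrix, length(x$times),
              min(x$times), max(x$times),
              format(x$dose), x$route))
  invisible(x)
}

#' @export
as.data.frame.ct_profile <- function(x, ...) {
  data.frame(subject_id = x$subject_id, matrix = x$matrix,
             time_h = x$times, conc = x$conc, blq = x$blq,
             unit = x$unit, lloq = x$lloq,
             dose_umol_kg = x$dose, route = x$route,
             stringsAsFactors = FALSE)
}

# numeric (non-BLQ) samples of a profile, optionally restricted to t >= 0
quantifiable <- function(profile, postdose_only = FALSE) {
  keep <- !profile$blq
  if (postdose_only) keep <- keep & profile$times >= 0
  list(times = profile$times[keep], conc = profile$conc[keep])
}

#' Read concentration-time profiles from a long-format CSV
#'
#' Expected columns: `subject_id`, `matrix`, `time_h`, `conc`, `unit`,
#' `lloq`, `dose_umol_kg`, `route`. `conc` empty or `"BLQ"` marks a sample
#' below the limit of quantification. One [ct_profile] is built per
#' (subject_id, matrix) pair.
#'
#' @param path Path to a UTF-8 CSV file with `.` as decimal separator.
#' @return Named list of [ct_profile] objects (`"subject/matrix"` keys).
#' @export
read_profiles <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "matrix", "time_h", "conc", "unit", "lloq",
            "dose_umol_kg", "route")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  blq <- is.na(df$conc) | trimws(toupper(as.character(df$conc))) %in% c("", "BLQ")
  conc <- suppressWarnings(as.numeric(df$conc))
  conc[blq] <- NA_real_
  key <- paste(df$subject_id, df$matrix, sep = "/")
  out <- lapply(split(seq_len(nrow(df)), key), function(i) {
    i <- i[order(df$time_h[i])]
    ct_profile(times = df$time_h[i], conc = conc[i], blq = blq[i],
               subject_id = as.character(df$subject_id[i][1]),
               matrix = df$matrix[i][1], unit = df$unit[i][1],
               lloq = df$lloq[i][1], dose = df$dose_umol_kg[i][1],
               route = df$route[i][1])
  })
  out
}

#' Plasma or brain-homogenate binding parameters
#'
#' @param bound_percent Percent bound, in `[0, 100)`.
#' @param matrix `"plasma"` or `"brain_homogenate"`.
#' @return A `binding_params` object with the free fraction `fu` attached.
#' @examples
#' binding_params(93.8)$fu  # rat plasma free fraction 0.062
#' @export
binding_params <- function(bound_percent,
                           matrix = c("plasma", "brain_homogenate")) {
  matrix <- match.arg(matrix)
  if (!is.finite(bound_percent) || bound_percent < 0 || bound_percent >= 100)
    stop("`bound_percent` must lie in [0, 100): fu would be undefined at 100 %")
  structure(list(bound_percent = bound_percent,
                 fu = 1 - bound_percent / 100,
                 matrix = matrix),
            class = "binding_params")
}
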