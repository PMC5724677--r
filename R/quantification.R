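#' Fit a calibration line to an external standard series
#'
#' Ordinary least-squares regression of detector response on nominal
#' concentration, as used to establish linearity of external amino-acid /
#' taurine standard curves in each HPLC run. Replicate responses per
#' concentration level are allowed and enter the fit individually
#' (the calibration is unweighted).
#'
#' @param series A data frame with columns `conc_nM` (nominal concentration,
#'   nM, non-negative) and `response` (detector response, arbitrary
#'   fluorescence units, non-negative). Additional columns are ignored.
#' @param lod_nM,loq_nM Optional detection/quantification limits (e.g. from
#'   [detect_limits()]) to carry along in the result.
#'
#' @return An object of class `"calibration"`: a list with `slope`
#'   (response per nM), `intercept` (response), `r_squared`, `n_levels`,
#'   `n_points`, `lod_nM` and `loq_nM`.
#'
#' @details At least three distinct concentration levels are required for a
#'   meaningful coefficient of determination; two levels fit a line with
#'   `r_squared` fixed at 1 and are rejected. `r_squared` is the squared
#'   Pearson correlation between response and concentration.
#'
#' @examples
#' s <- data.frame(conc_nM = c(0, 1, 2), response = c(0, 10, 20))
#' fit_calibration(s)$slope # 10
#' @export
fit_calibration <- function(series, lod_nM = NA_real_, loq_nM = NA_real_) {
  stopifnot(is.data.frame(series), all(c("conc_nM", "response") %in% names(series)))
  conc <- as.numeric(series$conc_nM)
  resp <- as.numeric(series$response)
  if (anyNA(conc) || anyNA(resp)) {
    stop("calibration series contains missing values", call. = FALSE)
  }
  if (any(conc < 0) || any(resp < 0)) {
    stop("concentrations and responses must be non-negative", call. = FALSE)
  }
  n_levels <- length(unique(conc))
  if (n_levels < 2) {
    stop("calibration requires at least 2 distinct concentration levels", call. = FALSE)
  }
  if (stats::var(conc) == 0) {
    stop("degenerate design: zero variance in concentration", call. = FALSE)
  }
  if (n_levels < 3) {
    stop("calibration requires >= 3 distinct levels for a meaningful r_squared",
         call. = FALSE)
  }
  fit <- stats::lm(resp ~ conc)
  r2 <- if (stats::var(resp) == 0) 0 else stats::cor(conc, resp)^2
  structure(
    list(
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      r_squared = r2,
      n_levels = n_levels,
      n_points = length(conc),
      lod_nM = lod_nM,
      loq_nM = loq_nM
    ),
    class = "calibration"
  )
}

#' @export
print.calibration <- function(x, ...) {
  cat("Calibration line: response =",
      format(x$intercept, digits = 4), "+",
      format(x$slope, digits = 4), "x conc_nM\n")
  cat("  r^2 =", format(x$r_squared, digits = 4),
      " (", x$n_points, "points,", x$n_levels, "levels )\n")
  if (!is.na(x$lod_nM)) {
    cat("  LOD =", x$lod_nM, "nM, LOQ =", x$loq_nM, "nM\n")
  }
  invisible(x)
}

#' Quantify an analyte against a single-point internal standard
#'
#' Internal-standard quantification as used for taurine with
#' alpha-aminobutyric acid (AABA) added at known concentration: the analyte
#' concentration is the response ratio times the internal-standard
#' concentration, divided by the relative response factor measured on an
#' external standard run. Because only the response ratio enters, common
#' multiplicative drift (injection volume, derivatization yield) cancels.
#'
#' @param sample_response Analyte peak response in the sample.
#' @param is_response Internal-standard peak response in the same injection;
#'   must be positive (a non-positive value signals a lost internal standard).
#' @param is_conc_nM Concentration of internal standard added (nM).
#' @param rrf Relative response factor, (analyte response per nM) /
#'   (internal-standard response per nM), from an external standard run.
#'
#' @return Analyte concentration in nM.
#' @examples
#' quantify_internal_standard(300, 100, 1, rrf = 1.5) # 2 nM
#' @export
quantify_internal_standard <- function(sample_response, is_response, is_conc_nM, rrf = 1) {
  if (!all(is.finite(c(sample_response, is_response, is_conc_nM, rrf)))) {
    stop("non-finite input", call. = FALSE)
  }
  if (is_response <= 0) {
    stop("internal standard failure: non-positive internal-standard response",
         call. = FALSE)
  }
  if (rrf <= 0) stop("relative response factor must be positive", call. = FALSE)
  (sample_response / is_response) * is_conc_nM / rrf
}

#' Spike recovery
#'
#' Recovery R (%) of a known standard addition:
#' `R = (Ca - Cu) / Cs * 100`, where `Ca` and `Cu` are the measured
#' concentrations of amended and unamended sample and `Cs` the added spike.
#'
#' @param c_amended,c_unamended Measured concentrations (nM) with and without
#'   the spike.
#' @param c_spike Spike concentration added (nM); must be positive.
#' @return Recovery in percent.
#' @examples
#' recovery(1.25, 0.25, 1) # 100
#' @export
recovery <- function(c_amended, c_unamended, c_spike) {
  if (any(c_spike <= 0)) stop("spike concentration must be positive", call. = FALSE)
  (c_amended - c_unamended) / c_spike * 100
}

#' Relative standard deviation of replicate measurements
#'
#' Method precision as RSD (%): the sample standard deviation (n - 1
#' denominator) of replicate concentrations divided by their mean.
#'
#' @param replicate_concs Numeric vector of at least two replicate
#'   concentrations with non-zero mean.
#' @return RSD in percent.
#' @examples
#' rsd(c(9, 11)) # 14.14
#' @export
rsd <- function(replicate_concs) {
  x <- as.numeric(replicate_concs)
  if (length(x) < 2) stop("RSD requires >= 2 replicates", call. = FALSE)
  m <- mean(x)
  if (m == 0) stop("RSD undefined: replicate mean is zero", call. = FALSE)
  stats::sd(x) / m * 100
}

#' Detection and quantification limits from a dilution series
#'
#' LOD and LOQ are the lowest concentrations of a standard dilution series at
#' which the signal-to-noise ratio reaches 3 and 10, respectively.
#'
#' @param dilution_series Data frame with columns `conc_nM`, `signal` and
#'   `noise` (noise must be positive). The series is sorted by concentration
#'   internally.
#' @return A list with `lod_nM` and `loq_nM` (`loq_nM` is `NA` if no level
#'   reaches S/N 10).
#' @examples
#' d <- data.frame(conc_nM = c(0.02, 0.2, 2), signal = c(6, 60, 600), noise = 2)
#' detect_limits(d) # lod 0.02, loq 0.2
#' @export
detect_limits <- function(dilution_series) {
  stopifnot(is.data.frame(dilution_series),
            all(c("conc_nM", "signal", "noise") %in% names(dilution_series)))
  d <- dilution_series[order(dilution_series$conc_nM), , drop = FALSE]
  if (any(d$noise <= 0)) stop("noise must be positive", call. = FALSE)
  sn <- d$signal / d$noise
  i_lod <- which(sn >= 3)
  if (length(i_lod) == 0) {
    stop("limits not reached: no level attains signal-to-noise >= 3", call. = FALSE)
  }
  i_loq <- which(sn >= 10)
  list(
    lod_nM = d$conc_nM[min(i_lod)],
    loq_nM = if (length(i_loq)) d$conc_nM[min(i_loq)] else NA_real_
  )
}

#' Confirm a sub-LOQ measurement by standard addition
#'
#' Samples falling between LOD and LOQ are spiked with a known amount (1 nM
#' taurine in the field protocol); identification is confirmed when the
#' measured increment returns the spike within a relative tolerance.
#'
#' @param measured_unspiked,measured_spiked Measured concentrations (nM)
#'   before and after spiking.
#' @param spike Spike added (nM), positive.
#' @param tol_pct Acceptance window on the relative error of the returned
#'   spike, in percent (default 15, chosen to comfortably include a
#'   99--111% recovery band).
#' @return `TRUE` if `|increment - spike| / spike * 100 <= tol_pct`.
#' @examples
#' confirm_by_spike(0.25, 1.25, 1) # TRUE
#' @export
confirm_by_spike <- function(measured_unspiked, measured_spiked, spike, tol_pct = 15) {
  if (spike <= 0) stop("spike must be positive", call. = FALSE)
  if (tol_pct <= 0) stop("tolerance must be positive", call. = FALSE)
  abs((measured_spiked - measured_unspiked) - spike) / spike * 100 <= tol_pct
}

#' Per-analyte QC report from standard series and replicate tables
#'
#' Convenience wrapper producing one method-validation row per analyte:
#' calibration slope/intercept/r-squared, detection limits when `noise` is
#' supplied, and (optionally) precision from a replicate table.
#'
#' @param standards Data frame with columns `analyte`, `conc_nM`, `response`
#'   and optionally `noise`.
#' @param replicates Optional data frame with columns `analyte` and `conc_nM`
#'   of replicate measurements for RSD.
#' @return A tibble with one row per analyte.
#' @export
qc_report <- function(standards, replicates = NULL) {
  stopifnot(all(c("analyte", "conc_nM", "response") %in% names(standards)))
  rows <- lapply(split(standards, standards$analyte), function(d) {
    lims <- if ("noise" %in% names(d) && !anyNA(d$noise)) {
      detect_limits(data.frame(conc_nM = d$conc_nM, signal = d$response,
                               noise = d$noise))
    } else {
      list(lod_nM = NA_real_, loq_nM = NA_real_)
    }
    cal <- fit_calibration(d, lod_nM = lims$lod_nM, loq_nM = lims$loq_nM)
    rsd_pct <- NA_real_
    if (!is.null(replicates)) {
      rep_d <- replicates$conc_nM[replicates$analyte == d$analyte[1]]
      if (length(rep_d) >= 2) rsd_pct <- rsd(rep_d)
    }
    tibble::tibble(
      analyte = d$analyte[1],
      slope = cal$slope, intercept = cal$intercept, r_squared = cal$r_squared,
      lod_nM = lims$lod_nM, loq_nM = lims$loq_nM, rsd_pct = rsd_pct
    )
  })
  dplyr::bind_rows(rows)
}
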