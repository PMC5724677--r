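#' Truncate an incubation time series at the release plateau
#'
#' Release rates are estimated only over the initial window during which the
#' dissolved pool still accumulates: the regression window ends at the time
#' point where the first tracked analyte (taurine or any amino acid from the
#' same chamber) stops increasing. A step counts as an increase when the
#' concentration rises by more than `tol_nM`.
#'
#' @param times_h Strictly increasing sampling times (h), starting at 0.
#' @param concs Concentrations (nM): a numeric vector for a single analyte,
#'   or a matrix/data frame with one column per analyte sharing the time
#'   grid.
#' @param tol_nM Minimum increase (nM) that still counts as a rise;
#'   default 0 (strict).
#' @return The truncation time `t_c` in hours: the last time point up to
#'   which every analyte increased at every step.
#' @examples
#' truncate_series(c(0, 2, 4, 6), c(1, 2, 3, 3)) # 4: flat 4 -> 6 step cut
#' @export
truncate_series <- function(times_h, concs, tol_nM = 0) {
  if (tol_nM < 0) stop("tol_nM must be >= 0", call. = FALSE)
  m <- as.matrix(concs)
  if (is.null(dim(concs))) m <- matrix(as.numeric(concs), ncol = 1)
  check_series(times_h, m)
  n <- length(times_h)
  if (n < 2) return(times_h[n])
  steps_ok <- vapply(seq_len(n - 1), function(i) {
    all(m[i + 1, ] - m[i, ] > tol_nM)
  }, logical(1))
  first_bad <- which(!steps_ok)
  if (length(first_bad) == 0) times_h[n] else times_h[min(first_bad)]
}

check_series <- function(times_h, m) {
  if (length(times_h) != nrow(m)) {
    stop("times and concentrations have different lengths", call. = FALSE)
  }
  if (any(diff(times_h) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (any(m < 0, na.rm = TRUE)) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  invisible(TRUE)
}

#' Fit a release rate by least-squares regression
#'
#' Ordinary least-squares regression of concentration (nM) on incubation
#' time (h). The slope is the volumetric release rate; its significance is
#' the two-sided t-test on the slope with n - 2 degrees of freedom.
#' Duplicate time points are averaged before fitting.
#'
#' @param times_h Sampling times in hours.
#' @param conc_nM Concentrations in nM.
#' @param conf_level Confidence level for the slope interval (default 0.95).
#' @return A list of class `"rate_fit"`: `slope_nM_h`, `intercept_nM`,
#'   `r_squared`, `p_value`, `se_slope`, `ci_lower`, `ci_upper`, `n`,
#'   `t_c_h` (last time point used). For a constant series the slope is 0 and
#'   `r_squared`/`p_value` are `NA` (flagged `low_fit` downstream).
#' @examples
#' fit_release_rate(0:4, 1 + 2 * (0:4))$slope_nM_h # 2
#' @export
fit_release_rate <- function(times_h, conc_nM, conf_level = 0.95) {
  d <- average_duplicate_times(times_h, conc_nM)
  t <- d$time_h
  y <- d$conc_nM
  if (length(t) < 3) {
    stop("insufficient points: release-rate regression needs >= 3 time points",
         call. = FALSE)
  }
  if (stats::var(y) == 0) {
    return(structure(
      list(slope_nM_h = 0, intercept_nM = y[1], r_squared = NA_real_,
           p_value = NA_real_, se_slope = NA_real_, ci_lower = NA_real_,
           ci_upper = NA_real_, n = length(t), t_c_h = max(t)),
      class = "rate_fit"
    ))
  }
  fit <- stats::lm(y ~ t)
  # noiseless series are valid inputs (synthetic closures); keep the p-value
  # machinery quiet about them
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  co <- sm$coefficients
  se <- co["t", "Std. Error"]
  slope <- co["t", "Estimate"]
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df = length(t) - 2)
  structure(
    list(
      slope_nM_h = unname(slope),
      intercept_nM = unname(co["(Intercept)", "Estimate"]),
      r_squared = sm$r.squared,
      p_value = unname(co["t", "Pr(>|t|)"]),
      se_slope = unname(se),
      ci_lower = unname(slope - tcrit * se),
      ci_upper = unname(slope + tcrit * se),
      n = length(t),
      t_c_h = max(t)
    ),
    class = "rate_fit"
  )
}

average_duplicate_times <- function(times_h, conc_nM) {
  if (length(times_h) != length(conc_nM)) {
    stop("times and concentrations have different lengths", call. = FALSE)
  }
  agg <- tapply(as.numeric(conc_nM), as.numeric(times_h), mean)
  data.frame(time_h = as.numeric(names(agg)), conc_nM = as.numeric(agg))
}

#' @export
print.rate_fit <- function(x, ...) {
  cat("Release-rate fit: slope =", format(x$slope_nM_h, digits = 4),
      "nM/h, r^2 =", format(x$r_squared, digits = 3),
      ", p =", format(x$p_value, digits = 3), ", n =", x$n, "\n")
  invisible(x)
}

#' Quality-control verdict for a release-rate fit
#'
#' A fitted rate is excluded when the regression is weak
#' (`r_squared < r2_min` or `p_value > p_max`, with the combinator
#' configurable), or when the release happened essentially at the start of
#' the incubation — a handling-stress signature: the first-interval increase
#' exceeds the summed increase over all later intervals and the
#' post-first-interval slope is non-positive.
#'
#' @param fit A `"rate_fit"` from [fit_release_rate()].
#' @param times_h,conc_nM The series the fit was computed on (used for the
#'   early-release pattern check).
#' @param r2_min Minimum acceptable r-squared (default 0.60).
#' @param p_max Maximum acceptable slope p-value (default 0.05).
#' @param combine `"or"` (default): exclude when either threshold fails;
#'   `"and"`: exclude only when both fail.
#' @return One of `"pass"`, `"low_fit"`, `"early_release_only"`,
#'   `"insufficient_points"`.
#' @export
apply_qc <- function(fit, times_h, conc_nM, r2_min = 0.60, p_max = 0.05,
                     combine = c("or", "and")) {
  combine <- match.arg(combine)
  d <- average_duplicate_times(times_h, conc_nM)
  if (nrow(d) < 3) return("insufficient_points")
  y <- d$conc_nM
  t <- d$time_h

  first_rise <- y[2] - y[1]
  later_rise <- y[length(y)] - y[2]
  post_slope <- if (length(t) >= 4 && stats::var(t[-1]) > 0) {
    unname(stats::coef(stats::lm(y[-1] ~ t[-1]))[2])
  } else {
    (y[length(y)] - y[2]) / (t[length(t)] - t[2])
  }
  if (first_rise > later_rise && first_rise > 0 && post_slope <= 0) {
    return("early_release_only")
  }

  r2 <- fit$r_squared
  p <- fit$p_value
  if (is.na(r2) || is.na(p)) return("low_fit")
  weak <- if (combine == "or") (r2 < r2_min) || (p > p_max) else
    (r2 < r2_min) && (p > p_max)
  if (weak) "low_fit" else "pass"
}

#' Normalise a volumetric release rate to per-individual and per-biomass
#'
#' Converts the regression slope (nM h^-1 in the chamber) into a
#' per-individual rate (pmol individual^-1 h^-1) and a carbon-biomass
#' specific rate (umol g^-1 C h^-1): total release is slope x chamber volume
#' (nmol h^-1).
#'
#' @param slope_nM_h Volumetric slope, nM h^-1.
#' @param volume_L Chamber volume in litres (field protocol: 0.5 L).
#' @param n_individuals Number of incubated individuals (> 0).
#' @param total_biomass_gC Total carbon biomass of the incubated specimens,
#'   grams C (> 0).
#' @return List with `total_nmol_h`, `rate_pmol_ind_h` and `rate_umol_gC_h`.
#' @examples
#' normalize_rates(31.68, 0.5, 50, 0.0176) # 316.8 pmol/ind/h, 0.9 umol/gC/h
#' @export
normalize_rates <- function(slope_nM_h, volume_L = 0.5, n_individuals,
                            total_biomass_gC) {
  if (volume_L <= 0) stop("invalid chamber: volume must be positive", call. = FALSE)
  if (n_individuals <= 0 || total_biomass_gC <= 0) {
    stop("invalid chamber: individuals and biomass must be positive", call. = FALSE)
  }
  total_nmol_h <- slope_nM_h * volume_L
  list(
    total_nmol_h = total_nmol_h,
    rate_pmol_ind_h = total_nmol_h / n_individuals * 1e3,
    rate_umol_gC_h = total_nmol_h / total_biomass_gC * 1e-3
  )
}

#' Subtract a zooplankton-free control series
#'
#' Point-wise subtraction of the control incubation (0.2-um filtered
#' seawater without animals) from a sample series, floored at zero. The
#' control is linearly interpolated onto the sample time grid when the grids
#' differ. Off by default in the pipeline, which instead reports the control
#' slope alongside the sample fit (the measured rates are net release).
#'
#' @param series,control Data frames with columns `time_h` and `conc_nM`
#'   (and optionally `analyte`, which must match between the two).
#' @return `series` with `conc_nM` replaced by the control-corrected values.
#' @export
control_correct <- function(series, control) {
  stopifnot(all(c("time_h", "conc_nM") %in% names(series)),
            all(c("time_h", "conc_nM") %in% names(control)))
  if ("analyte" %in% names(series) && "analyte" %in% names(control)) {
    if (!identical(unique(series$analyte), unique(control$analyte))) {
      stop("pairing error: sample and control analytes differ", call. = FALSE)
    }
  }
  ctrl <- stats::approx(control$time_h, control$conc_nM, xout = series$time_h,
                        rule = 2)$y
  out <- series
  out$conc_nM <- pmax(series$conc_nM - ctrl, 0)
  out
}

#' Molar ratio of taurine to summed amino-acid release
#'
#' @param tau_rate Taurine release rate (any normalisation), > 0.
#' @param dfaa_rates Release rates of the individual dissolved free amino
#'   acids from the same chamber, same normalisation; only QC-passing rates
#'   should be supplied.
#' @return `tau_rate / sum(dfaa_rates)` (mol/mol).
#' @examples
#' tau_dfaa_ratio(1, c(2, 3, 5)) # 0.1
#' @export
tau_dfaa_ratio <- function(tau_rate, dfaa_rates) {
  if (length(dfaa_rates) == 0 || sum(dfaa_rates) <= 0) {
    stop("undefined ratio: no positive amino-acid release rates", call. = FALSE)
  }
  if (is.na(tau_rate) || tau_rate <= 0) {
    stop("undefined ratio: taurine rate must be positive", call. = FALSE)
  }
  tau_rate / sum(dfaa_rates)
}

#' Estimate release rates for every chamber and analyte
#'
#' End-to-end driver: for each incubation chamber (station x replicate), the
#' regression window is truncated where the first analyte stops increasing
#' ([truncate_series()]), each analyte is fitted over that window
#' ([fit_release_rate()]), QC'd ([apply_qc()]) and, for passing fits,
#' normalised to per-individual and per-carbon rates ([normalize_rates()]).
#' Control series are fitted separately and their slope reported alongside;
#' with `control_correct = TRUE` the interpolated control is subtracted from
#' each sample series before fitting.
#'
#' @param incubations Long-format data frame: `station`, `replicate`,
#'   `analyte`, `time_h`, `conc_nM`, and optionally `is_control` (logical).
#' @param chambers Data frame keyed by `station`, `replicate` with
#'   `volume_L`, `n_individuals`, `total_biomass_gC`.
#' @param tol_nM Plateau tolerance passed to [truncate_series()].
#' @param subtract_control Subtract the matching control series before
#'   fitting (default `FALSE`).
#' @param r2_min,p_max,combine QC thresholds, see [apply_qc()].
#' @return Tibble with one row per chamber x analyte: window (`t_c_h`,
#'   `t_i_h`, `n_points`), fit (`slope_nM_h`, `r_squared`, `p_value`),
#'   `qc_status`, normalised rates (`NA` unless `qc_status == "pass"`), and
#'   `control_slope_nM_h` where a control was available.
#' @export
estimate_release_rates <- function(incubations, chambers, tol_nM = 0,
                                   subtract_control = FALSE,
                                   r2_min = 0.60, p_max = 0.05,
                                   combine = c("or", "and")) {
  combine <- match.arg(combine)
  need <- c("station", "replicate", "analyte", "time_h", "conc_nM")
  stopifnot(all(need %in% names(incubations)))
  if (!"is_control" %in% names(incubations)) incubations$is_control <- FALSE

  ctrl <- incubations[incubations$is_control, , drop = FALSE]
  samp <- incubations[!incubations$is_control, , drop = FALSE]

  chamber_key <- interaction(samp$station, samp$replicate, drop = TRUE)
  out <- lapply(split(samp, chamber_key), function(ch) {
    meta <- chambers[chambers$station == ch$station[1] &
                       chambers$replicate == ch$replicate[1], , drop = FALSE]
    if (nrow(meta) != 1) {
      stop("no unique chamber metadata for station ", ch$station[1],
           " replicate ", ch$replicate[1], call. = FALSE)
    }
    st_ctrl <- ctrl[ctrl$station == ch$station[1], , drop = FALSE]

    by_analyte <- split(ch, ch$analyte)
    series <- lapply(by_analyte, function(a) {
      d <- average_duplicate_times(a$time_h, a$conc_nM)
      a_ctrl <- st_ctrl[st_ctrl$analyte == a$analyte[1], , drop = FALSE]
      ctrl_slope <- NA_real_
      if (nrow(a_ctrl) >= 3) {
        cf <- fit_release_rate(a_ctrl$time_h, a_ctrl$conc_nM)
        ctrl_slope <- cf$slope_nM_h
      }
      if (subtract_control && nrow(a_ctrl) >= 2) {
        d <- control_correct(d, data.frame(time_h = a_ctrl$time_h,
                                           conc_nM = a_ctrl$conc_nM))
      }
      list(data = d, ctrl_slope = ctrl_slope)
    })

    grid <- series[[1]]$data$time_h
    shared <- all(vapply(series, function(s)
      identical(s$data$time_h, grid), logical(1)))
    t_c <- if (shared) {
      truncate_series(grid, vapply(series, function(s) s$data$conc_nM,
                                   numeric(length(grid))), tol_nM = tol_nM)
    } else {
      NA_real_ # per-analyte truncation below when grids differ
    }

    rows <- lapply(names(series), function(an) {
      d <- series[[an]]$data
      t_i <- max(d$time_h)
      t_cut <- if (is.na(t_c)) truncate_series(d$time_h, d$conc_nM, tol_nM) else t_c
      keep <- d$time_h <= t_cut
      base <- tibble::tibble(
        station = ch$station[1], replicate = ch$replicate[1], analyte = an,
        t_c_h = t_cut, t_i_h = t_i, n_points = sum(keep),
        slope_nM_h = NA_real_, r_squared = NA_real_, p_value = NA_real_,
        qc_status = "insufficient_points",
        rate_pmol_ind_h = NA_real_, rate_umol_gC_h = NA_real_,
        control_slope_nM_h = series[[an]]$ctrl_slope
      )
      if (sum(keep) < 3) return(base)
      fit <- fit_release_rate(d$time_h[keep], d$conc_nM[keep])
      base$slope_nM_h <- fit$slope_nM_h
      base$r_squared <- fit$r_squared
      base$p_value <- fit$p_value
      base$qc_status <- apply_qc(fit, d$time_h[keep], d$conc_nM[keep],
                                 r2_min = r2_min, p_max = p_max,
                                 combine = combine)
      if (base$qc_status == "pass") {
        nr <- normalize_rates(fit$slope_nM_h, meta$volume_L,
                              meta$n_individuals, meta$total_biomass_gC)
        base$rate_pmol_ind_h <- nr$rate_pmol_ind_h
        base$rate_umol_gC_h <- nr$rate_umol_gC_h
      }
      base
    })
    dplyr::bind_rows(rows)
  })
  dplyr::bind_rows(out)
}

#' Summarise release rates by group
#'
#' Unweighted arithmetic mean and sample standard deviation of the
#' per-individual and per-biomass rates within each group, with the daily
#' per-individual form (pmol h^-1 x 24 / 1000 = nmol d^-1). Rows with a
#' `qc_status` column are filtered to `"pass"` first.
#'
#' @param rates Data frame with columns `rate_pmol_ind_h` and/or
#'   `rate_umol_gC_h` (e.g. from [estimate_release_rates()] or the shipped
#'   observation tables).
#' @param by Character vector of grouping column names.
#' @return Tibble with one row per group: `n`, means and sds of both
#'   normalisations, and `mean_nmol_ind_d`.
#' @export
summarize_rates <- function(rates, by) {
  stopifnot(all(by %in% names(rates)))
  if ("qc_status" %in% names(rates)) {
    rates <- rates[rates$qc_status == "pass", , drop = FALSE]
  }
  if (nrow(rates) == 0) stop("no passing rates to summarise", call. = FALSE)
  grp <- rates[by]
  key <- interaction(grp, drop = TRUE, sep = "\r")
  rows <- lapply(split(rates, key), function(d) {
    out <- tibble::as_tibble(d[1, by, drop = FALSE])
    out$n <- nrow(d)
    if ("rate_pmol_ind_h" %in% names(d)) {
      x <- d$rate_pmol_ind_h[!is.na(d$rate_pmol_ind_h)]
      out$mean_pmol_ind_h <- mean(x)
      out$sd_pmol_ind_h <- if (length(x) > 1) stats::sd(x) else NA_real_
      out$mean_nmol_ind_d <- mean(x) * 24 / 1e3
    }
    if ("rate_umol_gC_h" %in% names(d)) {
      x <- d$rate_umol_gC_h[!is.na(d$rate_umol_gC_h)]
      out$mean_umol_gC_h <- mean(x)
      out$sd_umol_gC_h <- if (length(x) > 1) stats::sd(x) else NA_real_
    }
    out
  })
  dplyr::bind_rows(rows)
}
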