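#' Dissolved organic nitrogen by difference
#'
#' DON is total dissolved nitrogen minus the dissolved inorganic nitrogen
#' species: `DON = TDN - (NO3 + NO2 + NH4)`. If any inorganic species is
#' missing DON cannot be computed and `NA` is returned; a negative
#' difference (analytical error) is also set to `NA` with a warning.
#'
#' @param tdn_uM,no3_uM,no2_uM,nh4_uM Concentrations in umol L^-1
#'   (vectorised).
#' @return DON in umol L^-1, `NA` where not computable.
#' @examples
#' compute_don(10, 5, 0.5, 0.5) # 4
#' @export
compute_don <- function(tdn_uM, no3_uM, no2_uM, nh4_uM) {
  don <- tdn_uM - (no3_uM + no2_uM + nh4_uM)
  neg <- !is.na(don) & don < 0
  if (any(neg)) {
    warning(sum(neg), " sample(s) with negative DON set to NA")
    don[neg] <- NA_real_
  }
  don
}

# taurine is C2H7NO3S: 2 carbon and 1 nitrogen atoms per molecule
TAU_C_PER_MOLECULE <- 2
TAU_N_PER_MOLECULE <- 1

#' Taurine-carbon contribution to the DOC pool
#'
#' Percentage of dissolved organic carbon accounted for by dissolved free
#' taurine, using 2 carbon atoms per taurine molecule:
#' `(2 x tau_nM x 1e-3) / doc_uM x 100`.
#'
#' @param tau_nM Dissolved free taurine, nM.
#' @param doc_uM Dissolved organic carbon, uM (> 0).
#' @return Percent of DOC.
#' @examples
#' tau_carbon_fraction(5, 80) # 0.0125
#' @export
tau_carbon_fraction <- function(tau_nM, doc_uM) {
  if (any(doc_uM <= 0, na.rm = TRUE)) {
    stop("DOC must be positive", call. = FALSE)
  }
  (TAU_C_PER_MOLECULE * tau_nM * 1e-3) / doc_uM * 100
}

#' Taurine-nitrogen contribution to the DON pool
#'
#' Percentage of dissolved organic nitrogen accounted for by dissolved free
#' taurine (1 nitrogen atom per molecule).
#'
#' @param tau_nM Dissolved free taurine, nM.
#' @param don_uM Dissolved organic nitrogen, uM (> 0).
#' @return Percent of DON.
#' @examples
#' tau_nitrogen_fraction(5, 4) # 0.125
#' @export
tau_nitrogen_fraction <- function(tau_nM, don_uM) {
  if (any(don_uM <= 0, na.rm = TRUE)) {
    stop("DON must be positive", call. = FALSE)
  }
  (TAU_N_PER_MOLECULE * tau_nM * 1e-3) / don_uM * 100
}

#' Assign samples to depth layers
#'
#' Partitions depth into epipelagic, mesopelagic and bathypelagic layers
#' using half-open intervals `[0, epi)`, `[epi, meso)`, `[meso, Inf)`.
#' Default boundaries 200 m and 1000 m.
#'
#' @param depth_m Depths in metres (>= 0), vectorised.
#' @param boundaries Length-2 increasing positive numeric:
#'   epipelagic/mesopelagic and mesopelagic/bathypelagic boundaries (m).
#' @return Factor with levels `epipelagic`, `mesopelagic`, `bathypelagic`.
#' @examples
#' assign_layer(c(100, 200, 4000))
#' @export
assign_layer <- function(depth_m, boundaries = c(200, 1000)) {
  stopifnot(length(boundaries) == 2, boundaries[1] > 0,
            boundaries[2] > boundaries[1])
  if (any(depth_m < 0, na.rm = TRUE)) stop("depth must be >= 0", call. = FALSE)
  cut(depth_m, breaks = c(0, boundaries, Inf), right = FALSE,
      labels = c("epipelagic", "mesopelagic", "bathypelagic"),
      include.lowest = TRUE)
}

#' Mean concentration within a layer or depth window
#'
#' Unweighted arithmetic mean over all station-depth samples in the window,
#' or a per-station trapezoidal depth integration averaged across stations
#' (`method = "trapezoid"`).
#'
#' @param profiles Data frame with columns `depth_m` and the variable, plus
#'   `station` for the trapezoidal method.
#' @param var Column to average (default `"tau_nM"`).
#' @param layer Optional layer name; selects samples via [assign_layer()].
#' @param depth_range Optional `c(min, max)` depth window in metres
#'   (inclusive); overrides `layer`.
#' @param method `"mean"` (default) or `"trapezoid"`.
#' @param boundaries Layer boundaries for `layer` selection.
#' @return Mean concentration (same units as `var`).
#' @examples
#' p <- data.frame(depth_m = c(10, 50), tau_nM = c(2, 3))
#' layer_mean_concentration(p, depth_range = c(0, 100)) # 2.5
#' @export
layer_mean_concentration <- function(profiles, var = "tau_nM", layer = NULL,
                                     depth_range = NULL,
                                     method = c("mean", "trapezoid"),
                                     boundaries = c(200, 1000)) {
  method <- match.arg(method)
  stopifnot(var %in% names(profiles), "depth_m" %in% names(profiles))
  d <- profiles[!is.na(profiles[[var]]) & !is.na(profiles$depth_m), , drop = FALSE]
  if (!is.null(depth_range)) {
    d <- d[d$depth_m >= depth_range[1] & d$depth_m <= depth_range[2], , drop = FALSE]
  } else if (!is.null(layer)) {
    d <- d[assign_layer(d$depth_m, boundaries) == layer, , drop = FALSE]
  }
  if (nrow(d) == 0) stop("no samples in the requested window", call. = FALSE)
  if (method == "mean") {
    return(mean(d[[var]]))
  }
  if (!"station" %in% names(d)) stop("trapezoid method needs a station column",
                                     call. = FALSE)
  per_station <- vapply(split(d, d$station), function(s) {
    s <- s[order(s$depth_m), , drop = FALSE]
    if (nrow(s) == 1) return(s[[var]][1])
    z <- s$depth_m
    y <- s[[var]]
    sum(diff(z) * (utils::head(y, -1) + utils::tail(y, -1)) / 2) / diff(range(z))
  }, numeric(1))
  mean(per_station)
}

#' Annotate a bottle table with layers, DON and taurine pool fractions
#'
#' @param bottles Data frame with columns `station`, `depth_m`, `tau_nM` and
#'   optionally `doc_uM`, `tdn_uM`, `no3_uM`, `no2_uM`, `nh4_uM`.
#' @param boundaries Layer boundaries in metres, see [assign_layer()].
#' @return Tibble: input columns plus `layer`, `don_uM` (where the nitrogen
#'   species permit), `tauC_pct_doc` and `tauN_pct_don`.
#' @export
annotate_profiles <- function(bottles, boundaries = c(200, 1000)) {
  stopifnot(all(c("depth_m", "tau_nM") %in% names(bottles)))
  out <- tibble::as_tibble(bottles)
  out$layer <- assign_layer(out$depth_m, boundaries)
  n_cols <- c("tdn_uM", "no3_uM", "no2_uM", "nh4_uM")
  out$don_uM <- if (all(n_cols %in% names(out))) {
    compute_don(out$tdn_uM, out$no3_uM, out$no2_uM, out$nh4_uM)
  } else {
    NA_real_
  }
  out$tauC_pct_doc <- if ("doc_uM" %in% names(out)) {
    ifelse(!is.na(out$doc_uM) & out$doc_uM > 0,
           TAU_C_PER_MOLECULE * out$tau_nM * 1e-3 / out$doc_uM * 100, NA_real_)
  } else {
    NA_real_
  }
  out$tauN_pct_don <- ifelse(!is.na(out$don_uM) & out$don_uM > 0,
                             TAU_N_PER_MOLECULE * out$tau_nM * 1e-3 /
                               out$don_uM * 100, NA_real_)
  out
}

#' Mann-Whitney U comparison of two sample sets
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test: exact distribution when
#' the smaller group has at most 8 observations and there are no ties,
#' normal approximation with tie correction otherwise. When all values in
#' both groups are identical the groups are indistinguishable and `p = 1`.
#'
#' @param a,b Numeric vectors, each non-empty.
#' @return List with `u_statistic` (for group `a`), `p_value`, `n_a`, `n_b`.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6)) # U = 0, p = 0.1
#' @export
mann_whitney <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (length(unique(c(a, b))) == 1) {
    return(list(u_statistic = length(a) * length(b) / 2, p_value = 1,
                n_a = length(a), n_b = length(b)))
  }
  ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- min(length(a), length(b)) <= 8 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = use_exact, correct = !use_exact)
  )
  list(u_statistic = unname(wt$statistic), p_value = wt$p.value,
       n_a = length(a), n_b = length(b))
}

#' Hedges g effect size
#'
#' Standardised mean difference with the pooled sample standard deviation
#' and the small-sample bias correction `J = 1 - 3 / (4 (n_a + n_b) - 9)`.
#' Returned as a magnitude (absolute value), the convention for reporting
#' effect sizes between experiments: values below 0.2 indicate small,
#' above 0.5 medium and above 0.8 strong effects.
#'
#' @param a,b Numeric vectors with `n_a + n_b >= 3` and positive pooled sd.
#' @return Non-negative effect size g.
#' @examples
#' hedges_g(c(1, 2, 3), c(2, 3, 4)) # 0.8
#' @export
hedges_g <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  n_a <- length(a)
  n_b <- length(b)
  if (n_a + n_b < 3 || n_a < 1 || n_b < 1) {
    stop("hedges_g needs at least 3 observations across two groups", call. = FALSE)
  }
  va <- if (n_a > 1) stats::var(a) else 0
  vb <- if (n_b > 1) stats::var(b) else 0
  sp2 <- ((n_a - 1) * va + (n_b - 1) * vb) / (n_a + n_b - 2)
  if (sp2 <= 0) stop("undefined effect size: zero pooled sd", call. = FALSE)
  d <- (mean(a) - mean(b)) / sqrt(sp2)
  j <- 1 - 3 / (4 * (n_a + n_b) - 9)
  abs(d * j)
}

#' Compare a variable between two depth layers
#'
#' Runs [mann_whitney()] and [hedges_g()] on the samples of two layers of an
#' annotated bottle table.
#'
#' @param bottles Output of [annotate_profiles()] (needs a `layer` column)
#'   or any data frame with `layer` and the variable.
#' @param var Column to compare (default `"tau_nM"`).
#' @param layers Length-2 character vector of layer names.
#' @return Tibble with one row: the layers, group sizes, `u_statistic`,
#'   `p_value` and `hedges_g`.
#' @export
compare_layers <- function(bottles, var = "tau_nM",
                           layers = c("epipelagic", "mesopelagic")) {
  stopifnot("layer" %in% names(bottles), var %in% names(bottles),
            length(layers) == 2)
  a <- bottles[[var]][bottles$layer == layers[1]]
  b <- bottles[[var]][bottles$layer == layers[2]]
  mw <- mann_whitney(a, b)
  tibble::tibble(
    group_a = layers[1], group_b = layers[2],
    n_a = mw$n_a, n_b = mw$n_b,
    u_statistic = mw$u_statistic, p_value = mw$p_value,
    hedges_g = hedges_g(a, b)
  )
}
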