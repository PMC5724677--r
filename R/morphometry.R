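#' Carbon conversion factors (pg C per cubic micrometre)
#'
#' Default biovolume-to-carbon conversion factors: 0.08 pg C um^-3 for
#' copepods and 0.05 pg C um^-3 for amphipods. Such factors are instrument-
#' and fixation-dependent, so every morphometry function accepts an override.
#'
#' @return Named numeric vector of pg C um^-3 factors.
#' @export
default_carbon_factors <- function() {
  c(copepod = 0.08, amphipod = 0.05)
}

#' Ellipsoid biovolume
#'
#' Volume of an ellipsoid, `V = 4/3 * pi * a * b * c`, with `a`, `b`, `c` the
#' semi-axes in micrometres. Copepod bodies are modelled as prolate ellipsoids
#' with `a = length/2` and `b = c = diameter/2`; note that reading `a`, `b`,
#' `c` as full axes instead would inflate volumes eight-fold.
#'
#' @param a,b,c Semi-axes in um, all positive.
#' @return Volume in um^3.
#' @examples
#' ellipsoid_volume(1, 1, 1) # unit sphere, 4.18879
#' @export
ellipsoid_volume <- function(a, b, c) {
  if (any(c(a, b, c) <= 0)) {
    stop("invalid measurement: ellipsoid semi-axes must be positive", call. = FALSE)
  }
  4 / 3 * pi * a * b * c
}

#' Cone biovolume
#'
#' Volume of a cone, `V = 1/3 * pi * r^2 * h`. Amphipod bodies are modelled
#' as cones tapering along their length: `r = diameter/2`, `h = length`.
#'
#' @param r Base radius in um, positive.
#' @param h Height in um, positive.
#' @return Volume in um^3.
#' @examples
#' cone_volume(1, 3) # pi
#' @export
cone_volume <- function(r, h) {
  if (any(c(r, h) <= 0)) {
    stop("invalid measurement: cone dimensions must be positive", call. = FALSE)
  }
  1 / 3 * pi * r^2 * h
}

#' Biovolume of a specimen from length and diameter
#'
#' Applies the group-specific geometric model: ellipsoid for copepods
#' (`a = length/2`, `b = c = diameter/2`), cone for amphipods
#' (`r = diameter/2`, `h = length`).
#'
#' @param length_um,diameter_um Body length and diameter in um, positive.
#' @param group `"copepod"` or `"amphipod"` (vectorised).
#' @return Biovolume in um^3.
#' @export
specimen_biovolume <- function(length_um, diameter_um, group) {
  if (any(length_um <= 0) || any(diameter_um <= 0)) {
    stop("invalid measurement: length and diameter must be positive", call. = FALSE)
  }
  group <- match_group(group)
  ifelse(
    group == "copepod",
    4 / 3 * pi * (length_um / 2) * (diameter_um / 2)^2,
    1 / 3 * pi * (diameter_um / 2)^2 * length_um
  )
}

match_group <- function(group) {
  g <- tolower(as.character(group))
  bad <- !g %in% c("copepod", "amphipod")
  if (any(bad)) {
    stop("unknown taxonomic group: ", paste(unique(g[bad]), collapse = ", "),
         call. = FALSE)
  }
  g
}

#' Carbon biomass from biovolume
#'
#' @param biovolume_um3 Biovolume in um^3, positive.
#' @param group `"copepod"` or `"amphipod"` (vectorised with `biovolume_um3`).
#' @param factors Named vector of pg C um^-3 conversion factors; defaults to
#'   [default_carbon_factors()].
#' @return Carbon content in pg C per individual.
#' @examples
#' carbon_biomass(1000, "copepod") # 80 pg C
#' @export
carbon_biomass <- function(biovolume_um3, group, factors = default_carbon_factors()) {
  if (any(biovolume_um3 <= 0)) {
    stop("biovolume must be positive", call. = FALSE)
  }
  g <- tolower(as.character(group))
  missing_factor <- !g %in% names(factors)
  if (any(missing_factor)) {
    stop("missing carbon conversion factor for group: ",
         paste(unique(g[missing_factor]), collapse = ", "), call. = FALSE)
  }
  biovolume_um3 * unname(factors[g])
}

#' Biomass of a specimen set
#'
#' Converts a table of morphometric records into per-record biovolume and
#' carbon, and aggregates to the chamber totals needed to normalise release
#' rates: total individuals and total carbon biomass in grams
#' (1 pg = 1e-12 g).
#'
#' @param specimens Data frame with columns `taxon` (optional), `group`
#'   (`"copepod"`/`"amphipod"`), `length_um`, `diameter_um` and `count`
#'   (number of identical individuals the record represents, default 1).
#' @param factors Carbon conversion factors, see [carbon_biomass()].
#' @return A list of class `"biomass_result"`: `per_record` (tibble with
#'   `biovolume_um3` and `carbon_pg` per individual plus `carbon_pg_total`),
#'   `n_total`, `total_carbon_g` and `mean_individual_gC`.
#' @examples
#' sp <- data.frame(group = "copepod", length_um = 1000, diameter_um = 200,
#'                  count = 1)
#' specimen_set_biomass(sp)$total_carbon_g # ~1.68e-6 g C
#' @export
specimen_set_biomass <- function(specimens, factors = default_carbon_factors()) {
  stopifnot(is.data.frame(specimens))
  if (nrow(specimens) == 0) stop("empty specimen set", call. = FALSE)
  if (!all(c("group", "length_um", "diameter_um") %in% names(specimens))) {
    stop("specimens need columns group, length_um, diameter_um", call. = FALSE)
  }
  count <- if ("count" %in% names(specimens)) as.integer(specimens$count) else
    rep(1L, nrow(specimens))
  if (any(count < 1)) stop("count must be >= 1", call. = FALSE)

  vol <- specimen_biovolume(specimens$length_um, specimens$diameter_um,
                            specimens$group)
  cpg <- carbon_biomass(vol, specimens$group, factors)
  per_record <- tibble::tibble(
    taxon = if ("taxon" %in% names(specimens)) specimens$taxon else NA_character_,
    group = tolower(as.character(specimens$group)),
    length_um = specimens$length_um,
    diameter_um = specimens$diameter_um,
    count = count,
    biovolume_um3 = vol,
    carbon_pg = cpg,
    carbon_pg_total = cpg * count
  )
  n_total <- sum(count)
  total_carbon_g <- sum(per_record$carbon_pg_total) * 1e-12
  structure(
    list(
      per_record = per_record,
      n_total = n_total,
      total_carbon_g = total_carbon_g,
      mean_individual_gC = total_carbon_g / n_total
    ),
    class = "biomass_result"
  )
}

#' @export
print.biomass_result <- function(x, ...) {
  cat("Specimen set:", x$n_total, "individuals,",
      format(x$total_carbon_g * 1e6, digits = 4), "ug C total,",
      format(x$mean_individual_gC * 1e6, digits = 4), "ug C per individual\n")
  invisible(x)
}
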