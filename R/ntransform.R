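#' Net nitrogen mineralization from a paired-extraction incubation
#'
#' Change in total inorganic N (nitrate + ammonium) per gram dry soil per day
#' over an aerobic incubation, from KCl extractions at the start and end.
#' Negative values indicate net microbial immobilization and are reported
#' as-is.
#'
#' @param nitrate_t0,ammonium_t0 Initial NO3-N and NH4-N (ug N g dry soil-1).
#' @param nitrate_t28,ammonium_t28 Final pools (ug N g dry soil-1).
#' @param duration Incubation length (d, default 28).
#' @return Net mineralization rate (ug N g-1 d-1).
#' @export
#' @examples
#' net_mineralization(2, 4, 15, 3)
net_mineralization <- function(nitrate_t0, ammonium_t0, nitrate_t28,
                               ammonium_t28, duration = 28) {
  stopifnot(all(nitrate_t0 >= 0), all(ammonium_t0 >= 0),
            all(nitrate_t28 >= 0), all(ammonium_t28 >= 0), all(duration > 0))
  ((nitrate_t28 + ammonium_t28) - (nitrate_t0 + ammonium_t0)) / duration
}

#' Net nitrification from a paired-extraction incubation
#'
#' Change in NO3-N alone per gram dry soil per day over the incubation.
#'
#' @inheritParams net_mineralization
#' @return Net nitrification rate (ug N g-1 d-1).
#' @export
net_nitrification <- function(nitrate_t0, nitrate_t28, duration = 28) {
  stopifnot(all(nitrate_t0 >= 0), all(nitrate_t28 >= 0), all(duration > 0))
  (nitrate_t28 - nitrate_t0) / duration
}

#' Relative nitrification
#'
#' The percentage of net-mineralized N accumulating as nitrate over the
#' incubation. The default (`method = "delta"`) is the ratio of net
#' nitrification to net mineralization, which exceeds 100% when the ammonium
#' pool shrinks (nitrification outpacing mineralization). The alternative
#' `"end_pool"` reading is the nitrate share of the final inorganic pool.
#'
#' @inheritParams net_mineralization
#' @param method `"delta"` (default) or `"end_pool"`.
#' @return Percent. `NA` (with no error) when the delta denominator, net
#'   mineralization, is zero.
#' @export
relative_nitrification <- function(nitrate_t0, ammonium_t0, nitrate_t28,
                                   ammonium_t28, duration = 28,
                                   method = c("delta", "end_pool")) {
  method <- match.arg(method)
  if (method == "end_pool") {
    total <- nitrate_t28 + ammonium_t28
    return(ifelse(total > 0, 100 * nitrate_t28 / total, NA_real_))
  }
  minz <- net_mineralization(nitrate_t0, ammonium_t0, nitrate_t28,
                             ammonium_t28, duration)
  nitr <- net_nitrification(nitrate_t0, nitrate_t28, duration)
  ifelse(minz != 0, 100 * nitr / minz, NA_real_)
}

#' Transformation rates for a table of incubation assays
#'
#' @param assays Data frame with columns `nitrate_t0`, `ammonium_t0`,
#'   `nitrate_t28`, `ammonium_t28` and optionally `duration` (default 28 d).
#' @param method Relative-nitrification reading, see
#'   [relative_nitrification()].
#' @return The input with `net_mineralization`, `net_nitrification` and
#'   `relative_nitrification_pct` appended.
#' @export
n_transform_rates <- function(assays, method = c("delta", "end_pool")) {
  method <- match.arg(method)
  assays <- tibble::as_tibble(assays)
  dur <- if (is.null(assays[["duration"]])) 28 else assays$duration
  dplyr::mutate(
    assays,
    net_mineralization = net_mineralization(
      .data$nitrate_t0, .data$ammonium_t0,
      .data$nitrate_t28, .data$ammonium_t28, dur),
    net_nitrification = net_nitrification(
      .data$nitrate_t0, .data$nitrate_t28, dur),
    relative_nitrification_pct = relative_nitrification(
      .data$nitrate_t0, .data$ammonium_t0,
      .data$nitrate_t28, .data$ammonium_t28, dur, method = method)
  )
}

#' Water-filled pore space of a soil
#'
#' @param gravimetric_moisture Water content (g water per g dry soil).
#' @param bulk_density Soil bulk density (g cm-3).
#' @param porosity Total pore volume fraction, in (0, 1).
#' @return WFPS as a fraction of pore volume.
#' @export
wfps <- function(gravimetric_moisture, bulk_density, porosity) {
  stopifnot(all(gravimetric_moisture >= 0), all(bulk_density > 0),
            all(porosity > 0), all(porosity < 1))
  gravimetric_moisture * bulk_density / porosity
}

#' Water addition needed to reach a target WFPS
#'
#' Volume of water to add to a soil sample so its water-filled pore space
#' reaches the target (e.g. 0.6 for mineralization incubations, 1.0 for
#' fixation assays). Returns 0, flagged, when the soil is already wetter
#' than the target.
#'
#' @inheritParams wfps
#' @param dry_mass Sample dry mass (g).
#' @param target_wfps Target WFPS fraction, in (0, 1].
#' @return Water volume to add (mL; density 1 g mL-1), with logical
#'   attribute `"over_wet"` marking samples above the target.
#' @export
#' @examples
#' water_to_target_wfps(0.15, 1.3, 0.509, dry_mass = 10, target_wfps = 0.6)
water_to_target_wfps <- function(gravimetric_moisture, bulk_density, porosity,
                                 dry_mass, target_wfps) {
  stopifnot(all(target_wfps > 0), all(target_wfps <= 1), all(dry_mass > 0))
  current <- wfps(gravimetric_moisture, bulk_density, porosity)
  add <- dry_mass * (target_wfps * porosity / bulk_density -
                       gravimetric_moisture)
  over <- current > target_wfps
  out <- pmax(add, 0)
  attr(out, "over_wet") <- over
  out
}

#' Extract concentration to soil-mass basis
#'
#' Converts a KCl-extract analyte concentration (mg N L-1) to a per-gram
#' dry-soil amount, assuming complete extraction.
#'
#' @param mg_per_l Analyte concentration in the extract (mg N L-1).
#' @param extract_volume_l Extractant volume (L).
#' @param dry_mass_g Dry soil mass extracted (g).
#' @return ug N per g dry soil.
#' @export
extract_to_soil_conc <- function(mg_per_l, extract_volume_l, dry_mass_g) {
  stopifnot(all(extract_volume_l > 0), all(dry_mass_g > 0))
  mg_per_l * extract_volume_l / dry_mass_g * 1000
}
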