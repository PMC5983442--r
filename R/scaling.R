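#' Scaling parameters for annual areal fixation estimates
#'
#' Bundles the constants that convert per-gram incubation rates into annual
#' per-hectare N inputs: site soil properties, the glucose-stimulation
#' correction for soil assays, and the growing-season partition. The default
#' partition covers a 120-day season (roughly May through late August):
#' 20 d before fertilization, 40 d after, 60 d at peak biomass. Rates from
#' the post-senescence sampling are excluded from annual scaling by default;
#' supply an extra named element in `season_days` (e.g. `senescence = 30`)
#' to extend the season explicitly.
#'
#' @param bulk_density Soil bulk density (g cm-3).
#' @param core_depth Sampled core depth (cm).
#' @param glucose_factor Factor by which glucose solution addition inflated
#'   soil fixation in the laboratory assay (default 4.8); soil rates are
#'   divided by it. Root assays are not glucose-stimulated and are never
#'   corrected.
#' @param season_days Named numeric vector of days assigned to each sampling
#'   period.
#' @param root_biomass_areal Root biomass (g m-2) to the stated depth; used
#'   only for root scaling.
#' @return A `scaling_params` list.
#' @export
scaling_params <- function(bulk_density = 1.3, core_depth = 15,
                           glucose_factor = 4.8,
                           season_days = c(pre_fertilizer = 20,
                                           post_fertilizer = 40,
                                           peak_biomass = 60),
                           root_biomass_areal = NULL) {
  stopifnot(bulk_density > 0, core_depth > 0, glucose_factor > 0,
            length(season_days) >= 1, all(season_days > 0),
            !is.null(names(season_days)), all(nzchar(names(season_days))))
  if (!is.null(root_biomass_areal)) stopifnot(root_biomass_areal >= 0)
  structure(
    list(bulk_density = bulk_density, core_depth = core_depth,
         glucose_factor = glucose_factor, season_days = season_days,
         root_biomass_areal = root_biomass_areal),
    class = "scaling_params"
  )
}

# Season-weighted per-gram total (ug N g-1 yr-1) and its SE, shared by the
# soil and root scalers. Every period named in season_days must be present.
season_total <- function(rates, params) {
  periods <- names(params$season_days)
  missing_p <- setdiff(periods, rates$period)
  if (length(missing_p)) {
    stop("no rates for period(s): ", paste(missing_p, collapse = ", "),
         call. = FALSE)
  }
  rates <- rates[match(periods, rates$period), ]
  se <- rates[["rate_se"]] %||% rep(0, nrow(rates))
  days <- params$season_days
  list(total = sum(rates$rate_mean * days),
       se = sqrt(sum((se * days)^2)))
}

#' Annual soil fixation input per hectare
#'
#' Scales period-mean soil incubation rates (ug N g-1 d-1) to an annual
#' areal input: each period rate, divided by the glucose factor, times its
#' assigned days, summed over the season, then converted to a hectare basis
#' through bulk density x core depth (1 ug N g-1 over a 1-cm slab of density
#' 1 g cm-3 is 0.1 kg N ha-1). Period SEs propagate through the same linear
#' map in quadrature, assuming independent period samplings.
#'
#' @param rates Data frame with columns `period`, `rate_mean`
#'   (ug N g-1 d-1) and optionally `rate_se`. Must cover every period in
#'   `params$season_days`.
#' @param params A [scaling_params()] object.
#' @param glucose_correction Apply the glucose division (default `TRUE`,
#'   the soil-assay convention).
#' @return Tibble with `estimate_kg_n_ha` and `se_kg_n_ha`.
#' @export
#' @examples
#' r <- data.frame(period = c("pre_fertilizer", "post_fertilizer",
#'                            "peak_biomass"),
#'                 rate_mean = c(0.5, 0.3, 0.4))
#' annual_soil_anf(r, scaling_params(bulk_density = 1.3, core_depth = 15))
annual_soil_anf <- function(rates, params, glucose_correction = TRUE) {
  stopifnot(inherits(params, "scaling_params"))
  st <- season_total(rates, params)
  gf <- if (glucose_correction) params$glucose_factor else 1
  # ug g-1 yr-1 * g cm-3 * cm * 1e8 cm2 ha-1 * 1e-9 kg ug-1
  areal <- params$bulk_density * params$core_depth * 0.1
  tibble::tibble(
    estimate_kg_n_ha = st$total / gf * areal,
    se_kg_n_ha = st$se / gf * areal
  )
}

#' Annual root fixation input per hectare
#'
#' Scales period-mean root incubation rates through areal root biomass:
#' rate x days summed over the season, times g root m-2, times 1e4 m2 ha-1,
#' times 1e-9 kg ug-1. Root assays carry no glucose correction.
#'
#' @inheritParams annual_soil_anf
#' @return Tibble with `estimate_kg_n_ha` and `se_kg_n_ha`.
#' @export
annual_root_anf <- function(rates, params) {
  stopifnot(inherits(params, "scaling_params"))
  if (is.null(params$root_biomass_areal)) {
    stop("params$root_biomass_areal is required for root scaling",
         call. = FALSE)
  }
  st <- season_total(rates, params)
  conv <- params$root_biomass_areal * 1e4 * 1e-9
  tibble::tibble(
    estimate_kg_n_ha = st$total * conv,
    se_kg_n_ha = st$se * conv
  )
}

#' Aggregate vial-level rates to period means
#'
#' Collapses an [anf_rates()] table to one mean rate per period (optionally
#' within site/treatment groups), with the standard error across vials, in
#' the shape [annual_soil_anf()] and [annual_root_anf()] consume.
#'
#' @param rates An [anf_rates()] output table (needs `period` and
#'   `rate_per_gram`).
#' @param ... Additional grouping columns (tidy-select), e.g. `site`,
#'   `treatment_kg_n`.
#' @return Tibble with grouping columns, `period`, `rate_mean`, `rate_se`,
#'   `n`.
#' @export
period_rate_means <- function(rates, ...) {
  rates <- tibble::as_tibble(rates)
  dplyr::summarise(
    dplyr::group_by(rates, ..., .data$period),
    rate_mean = mean(.data$rate_per_gram),
    rate_se = stats::sd(.data$rate_per_gram) /
      sqrt(dplyr::n()),
    n = dplyr::n(),
    .groups = "drop"
  )
}
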