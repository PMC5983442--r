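# Canonical sampling periods of the seasonal design.
study_periods <- c("pre_fertilizer", "post_fertilizer", "peak_biomass",
                   "senescence")

# run code under a local, restored RNG state so simulation never disturbs
# the caller's stream
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

curve_spec <- function(family, ...) list(family = family,
                                         params = c(...))

default_curves <- function() {
  list(
    root_anf = list(
      MI = list(
        pre_fertilizer = curve_spec("exponential", a = 0.13, b = -0.01),
        post_fertilizer = curve_spec("power", a = 0.04, b = -0.59),
        # published slope -0.01 crosses zero inside the dose range; the
        # default keeps the intercept and flattens the slope to stay
        # non-negative through x = 196
        peak_biomass = curve_spec("linear", a = 1.67, b = -0.0085),
        senescence = curve_spec("exponential", a = 4.75, b = -0.03)
      ),
      WI = list(
        pre_fertilizer = curve_spec("exponential", a = 0.90, b = -0.01),
        post_fertilizer = curve_spec("constant", a = 0.5),
        peak_biomass = curve_spec("exponential", a = 0.45, b = -0.01),
        senescence = curve_spec("linear", a = 7.2, b = -0.03)
      )
    ),
    soil_anf = list(
      MI = list(
        pre_fertilizer = curve_spec("constant", a = 0.6),
        post_fertilizer = curve_spec("power", a = 0.54, b = -0.26),
        peak_biomass = curve_spec("power", a = 1.02, b = -0.11),
        senescence = curve_spec("constant", a = 0.5)
      ),
      WI = list(
        pre_fertilizer = curve_spec("constant", a = 0.9),
        post_fertilizer = curve_spec("linear", a = 0.99, b = -0.0023),
        peak_biomass = curve_spec("constant", a = 0.8),
        senescence = curve_spec("linear", a = 1.19, b = -0.003)
      )
    ),
    mineralization = list(
      MI = list(
        pre_fertilizer = curve_spec("constant", a = 0.30),
        post_fertilizer = curve_spec("power", a = 0.40, b = 0.14),
        peak_biomass = curve_spec("log", a = 0.07, c = 0.25),
        senescence = curve_spec("log", a = 0.04, c = 0.31)
      ),
      WI = list(
        pre_fertilizer = curve_spec("constant", a = 0.25),
        post_fertilizer = curve_spec("linear", a = 0.299, b = 0.002),
        peak_biomass = curve_spec("power", a = 0.127, b = 0.15),
        # published intercept is slightly negative; floored to 0 so the
        # curve is admissible over the whole dose range
        senescence = curve_spec("linear", a = 0, b = 0.0012)
      )
    )
  )
}

eval_curve_spec <- function(spec, x) {
  response_curve(spec$family, spec$params)(x)
}

#' Ground-truth parameters for a synthetic fixation study
#'
#' Defines the complete generating model for [simulate_study()]: the field
#' design (two contrasting sites, four blocks, fertilizer levels 0/56/196
#' kg N ha-1 yr-1, four seasonal sampling periods), the true dose-response
#' curves for root fixation, soil fixation and net mineralization at each
#' site and period, vial assay geometry, and measurement-noise levels.
#'
#' The default curves follow the published seasonal pattern: root fixation
#' declines with N addition (mostly exponentially) and spikes after plant
#' senescence (amplitude 4.75 ug N g-1 d-1 at the first site, decay -0.03
#' per kg N); soil fixation varies in a narrow 0.5-1 ug N g-1 d-1 band;
#' mineralization increases with N addition. Initial inorganic-N pools are
#' drawn around the published treatment-by-period means
#' ([table2_inorganic_n()]).
#'
#' @param sites Character vector of site labels (default `c("MI", "WI")`;
#'   curves are defined for these two).
#' @param n_blocks Number of field blocks (default 4).
#' @param treatments Fertilizer levels sampled (kg N ha-1 yr-1).
#' @param curves Nested list `curves[[variable]][[site]][[period]]` of
#'   `list(family, params)` curve specs; see Details for the defaults.
#' @param relative_nitrification Fraction of mineralized N accruing as
#'   nitrate in the incubation truth (default 0.9).
#' @param yield_truth Named list (by year) of quadratic-plateau yield
#'   parameters `c(a, b, c)`; default a single year with optimum
#'   109 kg N ha-1.
#' @param tissue_n_base,tissue_n_slope Tissue N% at 0 N and its rise per kg
#'   N fertilizer (defaults 0.52%/0.001).
#' @param deposition_kg_n Annual atmospheric deposition (default 6.2).
#' @param block_cv Lognormal coefficient of variation of multiplicative
#'   block effects on rates (default 0.15).
#' @param atom_pct_sd Gaussian instrument noise on atom% 15N
#'   (default 0.0002 atom%).
#' @param extract_cv Multiplicative CV on measured extract concentrations
#'   (default 0.1).
#' @param yield_cv Multiplicative CV on plot yields (default 0.07).
#' @param soil_total_n Named per-site soil total N mass fraction
#'   (g N per g soil).
#' @param root_total_n Root N mass fraction (default 0.005).
#' @param seed Default RNG seed used by [simulate_study()].
#' @return A validated `truth_params` list.
#' @export
truth_params <- function(sites = c("MI", "WI"), n_blocks = 4,
                         treatments = c(0, 56, 196),
                         curves = default_curves(),
                         relative_nitrification = 0.9,
                         yield_truth = list(
                           `2015` = c(a = 10.9, b = 0.03670,
                                      c = -0.0001683)),
                         tissue_n_base = 0.52, tissue_n_slope = 0.001,
                         deposition_kg_n = 6.2,
                         block_cv = 0.15, atom_pct_sd = 2e-4,
                         extract_cv = 0.1, yield_cv = 0.07,
                         soil_total_n = c(MI = 0.0008, WI = 0.0019),
                         root_total_n = 0.005,
                         seed = 1) {
  stopifnot(n_blocks >= 1, length(treatments) >= 2, all(treatments >= 0),
            block_cv >= 0, atom_pct_sd >= 0, extract_cv >= 0, yield_cv >= 0,
            relative_nitrification >= 0)
  truth <- structure(
    list(sites = sites, n_blocks = as.integer(n_blocks),
         treatments = treatments, periods = study_periods,
         curves = curves,
         relative_nitrification = relative_nitrification,
         yield_truth = yield_truth,
         tissue_n_base = tissue_n_base, tissue_n_slope = tissue_n_slope,
         deposition_kg_n = deposition_kg_n,
         block_cv = block_cv, atom_pct_sd = atom_pct_sd,
         extract_cv = extract_cv, yield_cv = yield_cv,
         soil_total_n = soil_total_n, root_total_n = root_total_n,
         seed = seed),
    class = "truth_params"
  )
  validate_truth(truth)
  truth
}

validate_truth <- function(truth) {
  xs <- seq(0, max(truth$treatments), length.out = 50)
  for (variable in names(truth$curves)) {
    for (site in truth$sites) {
      site_curves <- truth$curves[[variable]][[site]]
      if (is.null(site_curves)) {
        stop("no ", variable, " curves for site ", site, call. = FALSE)
      }
      for (period in truth$periods) {
        spec <- site_curves[[period]]
        if (is.null(spec)) {
          stop("no ", variable, " curve for ", site, "/", period,
               call. = FALSE)
        }
        if (any(eval_curve_spec(spec, xs) < 0)) {
          stop(variable, " curve for ", site, "/", period,
               " is negative on the dose range", call. = FALSE)
        }
      }
    }
  }
  invisible(truth)
}

#' Published initial inorganic-N pools by site, treatment and period
#'
#' Treatment-by-period means (with standard errors over 4 blocks) of
#' extractable NO3-N and NH4-N (ug N g dry soil-1) at the two study sites,
#' used by the generator to seed pre-incubation pools.
#'
#' @return Tibble with `site`, `treatment_kg_n`, `period`, `no3_mean`,
#'   `no3_se`, `nh4_mean`, `nh4_se`.
#' @export
table2_inorganic_n <- function() {
  tibble::tribble(
    ~site, ~treatment_kg_n, ~period, ~no3_mean, ~no3_se, ~nh4_mean, ~nh4_se,
    "WI", 0,   "pre_fertilizer",  2.59, 0.10,  6.65, 0.66,
    "WI", 0,   "post_fertilizer", 2.08, 0.48,  6.06, 1.05,
    "WI", 0,   "peak_biomass",    1.49, 0.26,  4.85, 0.50,
    "WI", 0,   "senescence",      1.54, 0.28,  3.53, 0.23,
    "WI", 56,  "pre_fertilizer",  3.66, 0.38,  7.02, 0.47,
    "WI", 56,  "post_fertilizer", 4.01, 0.31,  5.38, 0.44,
    "WI", 56,  "peak_biomass",    1.99, 0.20,  6.27, 0.68,
    "WI", 56,  "senescence",      2.43, 0.52,  4.39, 0.58,
    "WI", 196, "pre_fertilizer",  3.29, 0.26,  5.31, 0.24,
    "WI", 196, "post_fertilizer", 43.6, 16.7,  9.39, 3.63,
    "WI", 196, "peak_biomass",    12.7, 8.67,  6.38, 0.37,
    "WI", 196, "senescence",      3.44, 0.53,  3.32, 0.18,
    "MI", 0,   "pre_fertilizer",  2.44, 0.65,  3.77, 0.52,
    "MI", 0,   "post_fertilizer", 2.01, 0.13,  4.13, 0.48,
    "MI", 0,   "peak_biomass",    1.07, 0.23,  4.19, 0.63,
    "MI", 0,   "senescence",      1.20, 0.29,  3.26, 0.32,
    "MI", 56,  "pre_fertilizer",  3.13, 0.11,  3.21, 0.82,
    "MI", 56,  "post_fertilizer", 8.70, 0.94,  4.77, 0.65,
    "MI", 56,  "peak_biomass",    2.93, 1.56,  3.64, 0.20,
    "MI", 56,  "senescence",      3.59, 0.79,  2.64, 0.12,
    "MI", 196, "pre_fertilizer",  1.80, 0.49,  2.34, 0.51,
    "MI", 196, "post_fertilizer", 22.6, 8.74, 54.5, 11.04,
    "MI", 196, "peak_biomass",    3.20, 0.86,  2.87, 0.22,
    "MI", 196, "senescence",      10.6, 1.36,  2.47, 0.41
  )
}

# fixed vial assay protocol shared by generated soil and root incubations
vial_protocol <- function(sample_kind) {
  if (sample_kind == "soil") {
    list(dry_mass = 5, vial_volume = 12, removed_volume = 4,
         tracer_volume = 4.2, tracer_enrichment = 0.99, duration = 7)
  } else {
    list(dry_mass = 1, vial_volume = 12, removed_volume = 4,
         tracer_volume = 4.2, tracer_enrichment = 0.99, duration = 7)
  }
}

lognormal_effects <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a complete synthetic fixation study
#'
#' Generates raw measurement tables for every pipeline stage under a known
#' ground truth: vial-level isotope data (atom% 15N of tracer and control
#' incubations, produced by inverting the tracer rate equation around the
#' true rate), paired-extraction mineralization assays (final pools built
#' from the true mineralization rate and a relative-nitrification split),
#' and block-level plot yields from the plateau yield truth. Output is
#' deterministic given the seed.
#'
#' True per-sample rates (after multiplicative block effects) are returned
#' alongside, so recovery of truth by the analysis functions can be checked
#' at any noise level — exactly, when all noise parameters are zero.
#'
#' @param truth A [truth_params()] object.
#' @param seed RNG seed; defaults to `truth$seed`.
#' @return A `synthetic_study` list with tibbles `vials`, `assays`,
#'   `plot_blocks`, `plot_years` and a `truth` element holding the
#'   parameters plus per-sample true rates (`vial_truth`, `assay_truth`).
#' @export
#' @examples
#' study <- simulate_study(truth_params(), seed = 42)
#' names(study)
simulate_study <- function(truth, seed = truth$seed) {
  stopifnot(inherits(truth, "truth_params"))
  validate_truth(truth)
  with_local_seed(seed, {
    design <- expand.grid(
      site = truth$sites, block = seq_len(truth$n_blocks),
      treatment_kg_n = truth$treatments, period = truth$periods,
      stringsAsFactors = FALSE
    )
    design <- tibble::as_tibble(design)
    attr(design, "out.attrs") <- NULL

    # one multiplicative block effect per site x block x variable,
    # shared across treatments and periods (randomized complete block)
    vars <- c("root_anf", "soil_anf", "mineralization")
    be <- expand.grid(site = truth$sites, block = seq_len(truth$n_blocks),
                      variable = vars, stringsAsFactors = FALSE)
    be$effect <- lognormal_effects(nrow(be), truth$block_cv)
    block_effect <- function(site, block, variable) {
      be$effect[match(paste(site, block, variable),
                      paste(be$site, be$block, be$variable))]
    }

    nat <- 0.3663  # atom% 15N of air N2

    make_vials <- function(kind) {
      variable <- if (kind == "soil") "soil_anf" else "root_anf"
      proto <- vial_protocol(kind)
      d <- design
      d$sample_kind <- kind
      d$dry_mass <- proto$dry_mass
      d$total_n <- if (kind == "soil") {
        proto$dry_mass * truth$soil_total_n[d$site] * 1e6
      } else {
        rep(proto$dry_mass * truth$root_total_n * 1e6, nrow(d))
      }
      d$vial_volume <- proto$vial_volume
      d$occupied_volume <- occupied_volume_default(proto$dry_mass, kind)
      d$removed_volume <- proto$removed_volume
      d$tracer_volume <- proto$tracer_volume
      d$tracer_enrichment <- proto$tracer_enrichment
      d$duration <- proto$duration
      true_rate <- vapply(seq_len(nrow(d)), function(i) {
        spec <- truth$curves[[variable]][[d$site[i]]][[d$period[i]]]
        eval_curve_spec(spec, d$treatment_kg_n[i])
      }, numeric(1)) * block_effect(d$site, d$block, variable)
      ae_atm <- as.numeric(headspace_atom_excess(
        d$vial_volume, d$occupied_volume, d$removed_volume,
        d$tracer_volume, d$tracer_enrichment
      ))
      # invert the tracer equation: atom% difference implied by the rate
      delta_pct <- 100 * true_rate * d$dry_mass * ae_atm * d$duration /
        d$total_n
      noise <- function(n) stats::rnorm(n, 0, truth$atom_pct_sd)
      d$atom_pct_control <- nat + noise(nrow(d))
      d$atom_pct_treatment <- nat + delta_pct + noise(nrow(d))
      d$sample_id <- sprintf("%s_%s_%s_b%d_N%d", kind, d$site, d$period,
                             d$block, d$treatment_kg_n)
      d$true_rate_per_gram <- true_rate
      d
    }

    vials <- dplyr::bind_rows(make_vials("soil"), make_vials("root"))
    vial_truth <- vials[c("sample_id", "true_rate_per_gram")]
    vials$true_rate_per_gram <- NULL
    vials <- dplyr::relocate(vials, "sample_id")

    # mineralization assays: pools drawn about published means, final
    # pools from the true rate and the relative-nitrification split
    pools <- table2_inorganic_n()
    a <- design
    idx <- match(paste(a$site, a$treatment_kg_n, a$period),
                 paste(pools$site, pools$treatment_kg_n, pools$period))
    se_as_sd <- function(m, s) pmax(stats::rnorm(nrow(a), m, s * 2), 0.01)
    no3_t0 <- se_as_sd(pools$no3_mean[idx], pools$no3_se[idx])
    nh4_t0 <- se_as_sd(pools$nh4_mean[idx], pools$nh4_se[idx])
    true_min <- vapply(seq_len(nrow(a)), function(i) {
      spec <- truth$curves$mineralization[[a$site[i]]][[a$period[i]]]
      eval_curve_spec(spec, a$treatment_kg_n[i])
    }, numeric(1)) * block_effect(a$site, a$block, "mineralization")
    rel <- truth$relative_nitrification
    no3_t28 <- no3_t0 + rel * true_min * 28
    nh4_t28 <- pmax(nh4_t0 + (1 - rel) * true_min * 28, 0)
    # the realizable nitrification/mineralization truth after the NH4 floor
    true_nit <- (no3_t28 - no3_t0) / 28
    true_min_real <- ((no3_t28 + nh4_t28) - (no3_t0 + nh4_t0)) / 28
    mnoise <- function(v) v * (1 + stats::rnorm(length(v), 0,
                                                truth$extract_cv))
    a$nitrate_t0 <- pmax(mnoise(no3_t0), 0)
    a$ammonium_t0 <- pmax(mnoise(nh4_t0), 0)
    a$nitrate_t28 <- pmax(mnoise(no3_t28), 0)
    a$ammonium_t28 <- pmax(mnoise(nh4_t28), 0)
    a$duration <- 28
    a$sample_id <- sprintf("minz_%s_%s_b%d_N%d", a$site, a$period, a$block,
                           a$treatment_kg_n)
    assay_truth <- tibble::tibble(
      sample_id = a$sample_id,
      true_mineralization = true_min_real,
      true_nitrification = true_nit
    )
    assays <- dplyr::relocate(tibble::as_tibble(a), "sample_id")

    # plot yields: 8-level dose gradient, plateau truth per year
    levels8 <- seq(0, 196, by = 28)
    pb <- expand.grid(year = as.integer(names(truth$yield_truth)),
                      block = seq_len(truth$n_blocks),
                      fertilizer_kg_n = levels8, stringsAsFactors = FALSE)
    pb <- tibble::as_tibble(pb)
    attr(pb, "out.attrs") <- NULL
    mu <- vapply(seq_len(nrow(pb)), function(i) {
      pars <- truth$yield_truth[[as.character(pb$year[i])]]
      response_curve("quad_plateau", pars)(pb$fertilizer_kg_n[i])
    }, numeric(1))
    pb$yield_mg_ha <- pmax(mu * (1 + stats::rnorm(nrow(pb), 0,
                                                  truth$yield_cv)), 0)
    pb$tissue_n_pct <- truth$tissue_n_base +
      truth$tissue_n_slope * pb$fertilizer_kg_n
    pb$n_output_kg <- n_output_from_yield(pb$yield_mg_ha, pb$tissue_n_pct)

    plot_years <- dplyr::summarise(
      dplyr::group_by(pb, .data$year, .data$fertilizer_kg_n),
      yield_se = stats::sd(.data$yield_mg_ha) / sqrt(dplyr::n()),
      n_output_se = stats::sd(.data$n_output_kg) / sqrt(dplyr::n()),
      yield_mg_ha = mean(.data$yield_mg_ha),
      n_output_kg = mean(.data$n_output_kg),
      .groups = "drop"
    )
    plot_years$deposition_kg_n <- truth$deposition_kg_n

    structure(
      list(vials = vials, assays = assays, plot_blocks = pb,
           plot_years = plot_years,
           truth = list(params = truth, seed = seed,
                        vial_truth = vial_truth,
                        assay_truth = assay_truth)),
      class = "synthetic_study"
    )
  })
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("synthetic_study: ", nrow(x$vials), " vials, ", nrow(x$assays),
      " assays, ", nrow(x$plot_blocks), " plot-blocks (seed ",
      x$truth$seed, ")\n", sep = "")
  invisible(x)
}

#' Plot-year fixture generator
#'
#' Returns the packaged seven-year mass-balance input table for all three
#' sampled treatments (see [table1_mi()]); provided so synthetic studies
#' and the published ledger inputs come from one module surface.
#'
#' @return Tibble of 21 plot-year records.
#' @export
make_table1_fixture <- function() {
  table1_mi()
}
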