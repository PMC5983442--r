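test_that("headspace mixing model matches hand arithmetic and edge cases", {
  # 12 mL vial, nothing occupied, 4 mL removed, 4.2 mL tracer at 99%:
  # 4.2*0.99 / (4.2 + (12-4)*0.78) - 0.00366 = 0.3946
  ae <- headspace_atom_excess(12, 0, 4, 4.2, 0.99,
                              natural_abundance = 0.00366)
  expect_equal(as.numeric(ae), 4.158 / (4.2 + 6.24) - 0.00366,
               tolerance = 1e-12)

  # back-derived occupied volume for 5 g soil gives ~50% 15N2 headspace
  occ <- occupied_volume_default(5, "soil")
  expect_equal(occ, 5 / 1.9)
  ae2 <- as.numeric(headspace_atom_excess(12, occ, 4, 4.2, 0.99))
  expect_true(abs(ae2 - 0.5) < 0.03)

  # tracer at natural abundance and vanishing volume adds no excess
  suppressWarnings(ae3 <- headspace_atom_excess(12, 2, 4, 1e-12, 0.003663))
  expect_equal(as.numeric(ae3), 0, tolerance = 1e-10)

  # no headspace left is a geometry error
  expect_error(headspace_atom_excess(12, 10, 4, 1, 0.99),
               "geometry")
  # over-dilute tracer flags and clamps
  expect_warning(
    ae4 <- headspace_atom_excess(12, 0, 0, 0.001, 0.004),
    "dilute")
  expect_equal(as.numeric(ae4), 0)
  expect_true(attr(ae4, "dilute"))
})

test_that("headspace model conserves volume bookkeeping", {
  # final headspace = initial air headspace - removed + tracer, and the
  # N2 inventory is air N2 plus tracer volume
  vv <- 12; occ <- 2.5; rem <- 4; tr <- 4.2
  air <- vv - occ - rem
  ae <- headspace_atom_excess(vv, occ, rem, tr, 1, n2_fraction_air = 0.78,
                              natural_abundance = 0)
  total_n2 <- tr + air * 0.78
  expect_equal(as.numeric(ae), tr / total_n2, tolerance = 1e-12)
})

test_that("fixation rate reproduces the tracer equation oracle", {
  # AE_i 0.005, TN 5000, AE_atm 0.49, t 7 d, 5 g
  r <- fixation_rate(0.8663, 0.3663, total_n = 5000, dry_mass = 5,
                     duration = 7, ae_atm = 0.49)
  expect_equal(r$rate_per_vial, 0.005 * 5000 / (0.49 * 7),
               tolerance = 1e-12)
  expect_equal(r$rate_per_gram, r$rate_per_vial / 5, tolerance = 1e-12)
  expect_false(r$below_detection)

  # small excess case: AE_i 1e-4 (atom% diff 0.01), TN 1000, AE_atm 0.4
  r2 <- fixation_rate(0.3763, 0.3663, 1000, 1, 7, 0.4)
  expect_equal(r2$rate_per_gram, 1e-4 * 1000 / (0.4 * 7),
               tolerance = 1e-6)

  # zero excess is below detection, floored with raw retained
  r3 <- fixation_rate(0.3663, 0.3663, 5000, 5, 7, 0.49)
  expect_true(r3$below_detection)
  expect_identical(r3$rate_per_gram, 0)
  expect_identical(r3$raw_rate_per_gram, 0)

  # negative excess preserved raw, floored in the reported rate
  r4 <- fixation_rate(0.3600, 0.3663, 5000, 5, 7, 0.49)
  expect_true(r4$below_detection)
  expect_identical(r4$rate_per_gram, 0)
  expect_true(r4$raw_rate_per_gram < 0)

  expect_error(fixation_rate(0.4, 0.37, 5000, 5, 7, 0), "positive")
})

test_that("fixation rate is linear in excess and N, inverse in time and headspace", {
  base <- fixation_rate(0.4663, 0.3663, 2000, 2, 7, 0.4)
  # doubling both AE_i and TN quadruples the vial rate
  both <- fixation_rate(0.5663, 0.3663, 4000, 2, 7, 0.4)
  expect_equal(both$rate_per_vial, 4 * base$rate_per_vial,
               tolerance = 1e-12)
  # inverse linearity over a grid of t and AE_atm
  for (t in c(1, 3.5, 7, 14)) {
    for (ae in c(0.3, 0.4, 0.5)) {
      r <- fixation_rate(0.4663, 0.3663, 2000, 2, t, ae)
      expect_equal(r$rate_per_vial,
                   base$rate_per_vial * (7 / t) * (0.4 / ae),
                   tolerance = 1e-12)
    }
  }
})

test_that("contamination bound flags non-attributable rates", {
  expect_identical(contamination_bound(4.2, 0, 0.49, 7, 5), 0)
  b <- contamination_bound(4.2, 0.01, 0.49, 7, 5)
  expect_equal(b, 0.042 / (0.49 * 7 * 5), tolerance = 1e-12)
  # the study's minimum soil rate clears this worst-case bound
  expect_true(attributable(0.07, b))
  expect_false(attributable(b / 2, b))
})

test_that("anf_rates fills geometry defaults and appends result columns", {
  vials <- tibble::tibble(
    sample_id = c("a", "b"), sample_kind = c("soil", "root"),
    dry_mass = c(5, 1), total_n = c(4000, 5000),
    atom_pct_treatment = c(0.50, 0.40), atom_pct_control = 0.3663,
    vial_volume = 12, removed_volume = 4, tracer_volume = 4.2,
    tracer_enrichment = 0.99, duration = 7
  )
  out <- anf_rates(vials)
  expect_true(all(c("rate_per_gram", "ae_atm", "below_detection") %in%
                    names(out)))
  expect_equal(out$occupied_volume, c(5 / 1.9, 1))
  manual_ae <- as.numeric(headspace_atom_excess(12, 5 / 1.9, 4, 4.2, 0.99))
  expect_equal(out$ae_atm[1], manual_ae, tolerance = 1e-12)
})
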