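test_that("simulation is deterministic given a seed and leaves the RNG alone", {
  tp <- truth_params()
  a <- simulate_study(tp, seed = 11)
  b <- simulate_study(tp, seed = 11)
  expect_identical(a$vials, b$vials)
  expect_identical(a$assays, b$assays)
  expect_identical(a$plot_years, b$plot_years)
  c2 <- simulate_study(tp, seed = 12)
  expect_false(identical(a$vials$atom_pct_treatment,
                         c2$vials$atom_pct_treatment))
  # caller RNG stream is restored
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(simulate_study(tp, seed = 5)); after <- runif(1)
  expect_identical(before, after)
})

test_that("generated tables conform to the consuming schemas", {
  st <- simulate_study(truth_params(), seed = 2)
  expect_silent(validate_table(st$vials, "vials"))
  expect_silent(validate_table(st$assays, "minz_assays"))
  expect_equal(nrow(st$vials), 2 * 2 * 4 * 3 * 4)  # kinds x sites x blocks
  expect_setequal(unique(st$vials$period),
                  c("pre_fertilizer", "post_fertilizer", "peak_biomass",
                    "senescence"))
})

test_that("zero-noise studies are inverted exactly by the pipeline", {
  s0 <- simulate_study(truth_params(atom_pct_sd = 0, extract_cv = 0,
                                    yield_cv = 0), seed = 3)
  r0 <- anf_rates(s0$vials, detection_sd = 0)
  truth <- s0$truth$vial_truth$true_rate_per_gram
  pos <- truth > 0
  expect_lt(max(abs(r0$raw_rate_per_gram[pos] - truth[pos]) / truth[pos]),
            1e-10)
  tr <- n_transform_rates(s0$assays)
  expect_lt(max(abs(tr$net_mineralization -
                      s0$truth$assay_truth$true_mineralization)), 1e-10)
  expect_lt(max(abs(tr$net_nitrification -
                      s0$truth$assay_truth$true_nitrification)), 1e-10)
})

test_that("ensemble mean of simulated rates converges to the truth curve", {
  # law-of-large-numbers check on one site/period/dose cell
  tp <- truth_params(block_cv = 0.15)
  draws <- vapply(1:60, function(i) {
    st <- simulate_study(tp, seed = 4000 + i)
    r <- anf_rates(st$vials)
    sen <- r$sample_kind == "root" & r$site == "MI" &
      r$period == "senescence" & r$treatment_kg_n == 0
    mean(r$rate_per_gram[sen])
  }, numeric(1))
  truth_val <- 4.75 * exp(-0.03 * 1)
  expect_lt(abs(mean(draws) - truth_val) / truth_val, 0.08)
})

test_that("the seasonal design encodes the post-senescence root spike", {
  s0 <- simulate_study(truth_params(atom_pct_sd = 0, block_cv = 0),
                       seed = 5)
  r <- anf_rates(s0$vials)
  roots0 <- r[r$sample_kind == "root" & r$treatment_kg_n == 0 &
                r$site == "MI", ]
  sen <- mean(roots0$rate_per_gram[roots0$period == "senescence"])
  other <- max(roots0$rate_per_gram[roots0$period != "senescence"])
  expect_gt(sen, 2 * other)
})

test_that("mineralization truth rises with N and relative nitrification is high", {
  s0 <- simulate_study(truth_params(atom_pct_sd = 0, extract_cv = 0,
                                    block_cv = 0), seed = 6)
  tr <- n_transform_rates(s0$assays)
  post <- tr[tr$site == "MI" & tr$period == "post_fertilizer", ]
  m <- tapply(post$net_mineralization, post$treatment_kg_n, mean)
  expect_true(m["196"] > m["0"])
  # unfertilized rates across all periods sit in the reported band
  mi0 <- tr[tr$site == "MI" & tr$treatment_kg_n == 0, ]
  expect_true(all(mi0$net_mineralization >= 0.25 &
                    mi0$net_mineralization <= 0.70))
  expect_true(all(tr$relative_nitrification_pct > 80, na.rm = TRUE))
})

test_that("truth validation rejects curves that go negative on the dose range", {
  bad <- default_curves <- truth_params()
  bad$curves$root_anf$MI$peak_biomass <-
    list(family = "linear", params = c(a = 1.67, b = -0.02))
  expect_error(simulate_study(bad), "negative")
})

test_that("schema round-trip: written CSVs re-parse into equal tables", {
  st <- simulate_study(truth_params(), seed = 8)
  path <- tempfile(fileext = ".csv")
  write_pipeline_csv(st$assays, path, seed = 8)
  back <- validate_table(path, "minz_assays")
  expect_equal(tibble::as_tibble(back), st$assays, tolerance = 1e-12)
})
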