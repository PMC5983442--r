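test_that("each family recovers its generating parameters from noiseless data", {
  x <- dose8()
  cases <- list(
    list(fam = "linear", pars = c(a = 1, b = 0.01)),
    list(fam = "log", pars = c(a = 0.07, c = 0.25)),
    list(fam = "power", pars = c(a = 0.40, b = 0.14)),
    list(fam = "exponential", pars = c(a = 2, b = -0.01)),
    list(fam = "quad_plateau", pars = c(a = 2, b = 0.2, c = -0.001))
  )
  for (cs in cases) {
    y <- response_curve(cs$fam, cs$pars)(x)
    fit <- fit_family(data.frame(x = x, y = y), cs$fam)
    expect_true(fit$converged)
    expect_equal(unname(fit$params[names(cs$pars)]), unname(cs$pars),
                 tolerance = 1e-6)
    expect_true(fit$significant)
  }
})

test_that("noiseless plateau join equals the quadratic vertex", {
  x <- rep(dose8(), 2)
  for (x0 in c(50, 100, 109, 150)) {
    b <- 0.2; cc <- -b / (2 * x0)
    y <- response_curve("quad_plateau", c(a = 2, b = b, c = cc))(x)
    fit <- fit_family(data.frame(x = x, y = y), "quad_plateau")
    expect_equal(fit$optimum_n, x0, tolerance = 1e-4)
    # vertex formula from the fitted coefficients agrees
    expect_equal(-fit$params["b"] / (2 * fit$params["c"]),
                 c(b = x0), tolerance = 1e-4)
  }
})

test_that("plateau with non-negative curvature falls back to linear, optimum 0", {
  x <- dose8()
  y <- 1 + 0.005 * x + 0.00002 * x^2  # convex, no interior maximum
  fit <- fit_family(data.frame(x = x, y = y), "quad_plateau")
  expect_true(fit$fallback)
  expect_identical(fit$family, "linear")
  expect_identical(fit$optimum_n, 0)
})

test_that("AIC differences are invariant to common y-scaling up to the n log shift", {
  set.seed(31)
  d <- data.frame(x = dose12())
  d$y <- 0.40 * (d$x + 1)^0.14 + rnorm(12, 0, 0.05)
  fams <- c("linear", "log", "power", "exponential")
  aic1 <- vapply(fams, function(f) fit_family(d, f)$aic, numeric(1))
  d2 <- d; d2$y <- 10 * d$y
  aic2 <- vapply(fams, function(f) fit_family(d2, f)$aic, numeric(1))
  # scaling y by c shifts every AIC by 2n log(c); differences persist
  expect_equal(diff(aic1), diff(aic2), tolerance = 1e-3)
})

test_that("select_model keeps significant fits, picks lowest AIC, ties break canonically", {
  # strongly linear data select linear over curved families
  set.seed(7)
  d <- data.frame(x = dose12())
  d$y <- 1 + 0.01 * d$x + rnorm(12, 0, 0.01)
  best <- select_model(d)
  expect_identical(best$family, "linear")
  fits <- attr(best, "fits")
  sig_aics <- vapply(Filter(function(f) isTRUE(f$significant), fits),
                     function(f) f$aic, numeric(1))
  expect_equal(best$aic, min(sig_aics), tolerance = 1e-12)

  # flat data: nothing significant
  set.seed(8)
  d0 <- data.frame(x = dose12(), y = 5 + rnorm(12, 0, 0.1))
  expect_null(select_model(d0))
})

test_that("inverse-rank weights favour the most central replicate per level", {
  x <- rep(c(0, 56), each = 3)
  y <- c(1.0, 1.1, 3.0, 2.0, 2.05, 1.0)
  w <- inverse_rank_weights(x, y)
  # within each level weights are 1, 1/2, 1/3 by |deviation from median|
  expect_setequal(w[1:3], c(1, 1 / 2, 1 / 3))
  expect_equal(w[3], 1 / 3)  # the 3.0 outlier gets the smallest weight
  expect_equal(w[6], 1 / 3)
})

test_that("optimal N clamps to the dose range and returns 0 for flat yields", {
  x <- rep(dose8(), 2)
  # monotone increasing through the range: boundary clamp
  y <- response_curve("quad_plateau", c(a = 2, b = 0.2, c = -0.0004))(x)
  est <- optimal_n(data.frame(x = x, y = y))  # vertex at 250
  expect_equal(as.numeric(est), 196)
  expect_true(attr(est, "boundary"))
  # flat yields: no N effect, optimum 0
  set.seed(12)
  y0 <- 10 + rnorm(length(x), 0, 0.5)
  expect_identical(as.numeric(optimal_n(data.frame(x = x, y = y0))), 0)
  # noiseless responsive yields recover the join
  y109 <- response_curve("quad_plateau",
                         c(a = 10.9, b = 0.0367, c = -0.0367 / 218))(x)
  expect_equal(as.numeric(optimal_n(data.frame(x = x, y = y109))), 109,
               tolerance = 1e-3)
})

test_that("parameter recovery is nearly unbiased at survey-scale noise", {
  # 120 replicates per family at sigma 0.05, bias under 10% of magnitude
  x <- dose12()
  gens <- list(
    linear = c(a = 0.299, b = 0.002),
    power = c(a = 0.40, b = 0.14),
    exponential = c(a = 2, b = -0.01)
  )
  set.seed(21)
  for (fam in names(gens)) {
    f <- response_curve(fam, gens[[fam]])
    shape <- "b"
    ests <- replicate(120, {
      y <- f(x) + rnorm(12, 0, 0.05)
      fit <- fit_family(data.frame(x = x, y = y), fam)
      fit$params[[shape]]
    })
    truth <- gens[[fam]][[shape]]
    expect_lt(abs(mean(ests) - truth), 0.1 * abs(truth) + 0.002)
  }
})

test_that("failed or underdetermined fits are flagged, not thrown", {
  expect_error(fit_family(data.frame(x = c(0, 1), y = c(1, 2)), "linear"),
               "at least")
  # predict matches the curve on new doses
  x <- dose8()
  y <- 2 * exp(-0.01 * (x + 1))
  fit <- fit_family(data.frame(x = x, y = y), "exponential")
  expect_equal(predict(fit, newdata = c(10, 20)),
               2 * exp(-0.01 * (c(10, 20) + 1)), tolerance = 1e-5)
})
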