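# shared fixtures: the canonical dose design and published-curve truths
dose12 <- function() rep(c(0, 56, 196), each = 4)
dose8 <- function() seq(0, 196, by = 28)

# the four published family curves used as generating truths in
# model-selection checks (one per family)
caption_truths <- function() {
  list(
    power = response_curve("power", c(a = 0.40, b = 0.14)),
    log = response_curve("log", c(a = 0.07, c = 0.25)),
    linear = response_curve("linear", c(a = 0.299, b = 0.002)),
    exponential = response_curve("exponential", c(a = 4.75, b = -0.03))
  )
}

# AIC winner among the rate candidate families, ignoring significance
aic_winner <- function(d, candidates = c("linear", "log", "power",
                                         "exponential")) {
  aics <- vapply(candidates, function(fam) {
    z <- tryCatch(fit_family(d, fam), error = function(e) NULL)
    if (is.null(z) || !z$converged) Inf else z$aic
  }, numeric(1))
  candidates[which.min(aics)]
}

# a quiet zero-noise truth for exact round-trip checks
noiseless_truth <- function(...) {
  truth_params(atom_pct_sd = 0, extract_cv = 0, yield_cv = 0, ...)
}
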