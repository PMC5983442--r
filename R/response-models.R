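#' Response-model families
#'
#' The dose-response families used to describe how yields and N-cycling
#' rates respond to N addition level `x` (kg N ha-1 yr-1):
#'
#' * `linear`: `y = a + b*x`
#' * `log` (saturating): `y = a*log(x + 1) + c`
#' * `power`: `y = a*(x + 1)^b`
#' * `exponential`: `y = a*exp(b*(x + 1))`
#' * `quad_plateau`: `y = a + b*x + c*x^2` for `x < x0`, constant at
#'   `y(x0)` beyond, with the join (agronomic optimum) at `x0 = -b/(2c)`,
#'   `c < 0`
#'
#' The `x + 1` offsets keep the unfertilized (`x = 0`) treatment
#' well-defined under log and power transforms. `constant` (`y = a`) is
#' available for curve evaluation only.
#'
#' @format Character vector of family names in canonical (tie-break) order.
#' @export
response_families <- c("linear", "log", "power", "exponential",
                       "quad_plateau")

#' Evaluate a response curve
#'
#' Builds the mean function for a named family and parameter vector, as
#' used by the synthetic-data generator and by [predict.response_fit()].
#'
#' @param family One of [response_families] or `"constant"`.
#' @param params Named numeric parameters (see [response_families] for each
#'   family's parameterization; `constant` takes `a`).
#' @return A vectorized function of `x`.
#' @export
#' @examples
#' f <- response_curve("exponential", c(a = 4.75, b = -0.03))
#' f(c(0, 56, 196))
response_curve <- function(family, params) {
  params <- as.list(params)
  switch(
    family,
    constant = function(x) rep(params$a, length(x)),
    linear = function(x) params$a + params$b * x,
    log = function(x) params$a * log(x + 1) + params$c,
    power = function(x) params$a * (x + 1)^params$b,
    exponential = function(x) params$a * exp(params$b * (x + 1)),
    quad_plateau = function(x) {
      x0 <- -params$b / (2 * params$c)
      plateau <- params$a + params$b * x0 + params$c * x0^2
      ifelse(x < x0, params$a + params$b * x + params$c * x^2, plateau)
    },
    stop("unknown family: ", family, call. = FALSE)
  )
}

# Weighted SSE of y against fitted values.
wsse <- function(y, fitted, w) sum(w * (y - fitted)^2)

# Conditionally-linear profile fit: given a basis function g(b, x), the
# model y = a * g(b, x) is linear in a for fixed b. Profile b over a
# deterministic grid, refine the best grid point with stats::optimize.
profile_fit <- function(x, y, w, gfun, b_grid) {
  prof <- function(b) {
    g <- gfun(b, x)
    if (!all(is.finite(g))) return(list(sse = Inf, a = NA_real_))
    denom <- sum(w * g^2)
    if (denom <= 0 || !is.finite(denom)) {
      return(list(sse = Inf, a = NA_real_))
    }
    a <- sum(w * g * y) / denom
    list(sse = wsse(y, a * g, w), a = a)
  }
  sses <- vapply(b_grid, function(b) prof(b)$sse, numeric(1))
  if (!any(is.finite(sses))) return(NULL)
  i <- which.min(sses)
  lo <- b_grid[max(1, i - 1)]
  hi <- b_grid[min(length(b_grid), i + 1)]
  b <- if (lo < hi) {
    stats::optimize(function(b) prof(b)$sse, c(lo, hi), tol = 1e-10)$minimum
  } else {
    b_grid[i]
  }
  # keep the grid optimum if refinement did not improve
  if (prof(b)$sse > sses[i]) b <- b_grid[i]
  pr <- prof(b)
  list(b = b, a = pr$a, sse = pr$sse)
}

# Deterministic sign-symmetric log-spaced grid for rate-like parameters.
signed_log_grid <- function(lo = 1e-4, hi = 1, n = 21) {
  g <- exp(seq(log(lo), log(hi), length.out = n))
  sort(c(-rev(g), 0, g))
}

# Quadratic-plateau profile: given the join x0 (with the vertex constraint
# b = -2*c*x0) the model is linear in (a, c):
#   x <  x0: y = a + c * (x^2 - 2*x0*x)
#   x >= x0: y = a - c * x0^2
plateau_profile <- function(x, y, w, x0) {
  z <- ifelse(x < x0, x^2 - 2 * x0 * x, -x0^2)
  fit <- stats::lm.wfit(cbind(1, z), y, w)
  coefs <- fit$coefficients
  if (any(is.na(coefs))) return(list(sse = Inf))
  fitted <- coefs[1] + coefs[2] * z
  list(sse = wsse(y, fitted, w), a = unname(coefs[1]),
       c = unname(coefs[2]))
}

fit_quad_plateau <- function(x, y, w) {
  # a rising plateau needs concave curvature; convex data (unconstrained
  # quadratic curvature >= 0) signal the linear fallback
  unc <- stats::lm.wfit(cbind(1, x, x^2), y, w)$coefficients
  if (!any(is.na(unc)) && unc[3] >= 0) {
    return(list(a = unname(unc[1]), b = unname(unc[2]), c = unname(unc[3]),
                x0 = NA_real_, sse = NA_real_))
  }
  hi <- max(x) * 1.5
  x0_grid <- seq(max(min(x), 1e-6) + 1e-6, hi, length.out = 61)
  sses <- vapply(x0_grid, function(x0) plateau_profile(x, y, w, x0)$sse,
                 numeric(1))
  if (!any(is.finite(sses))) return(NULL)
  i <- which.min(sses)
  lo <- x0_grid[max(1, i - 1)]
  up <- x0_grid[min(length(x0_grid), i + 1)]
  x0 <- stats::optimize(function(x0) plateau_profile(x, y, w, x0)$sse,
                        c(lo, up), tol = 1e-9)$minimum
  if (plateau_profile(x, y, w, x0)$sse > sses[i]) x0 <- x0_grid[i]
  pr <- plateau_profile(x, y, w, x0)
  list(a = pr$a, b = -2 * pr$c * x0, c = pr$c, x0 = x0, sse = pr$sse)
}

# Parameter covariance from the numerical Jacobian of the mean function at
# the weighted least-squares optimum.
fit_param_inference <- function(x, y, w, family, params, shape_param) {
  n <- length(y)
  k <- length(params)
  df <- n - k
  f <- function(theta) {
    names(theta) <- names(params)
    response_curve(family, theta)(x)
  }
  out <- list(se = NA_real_, t = NA_real_, p = NA_real_)
  if (df <= 0) return(out)
  J <- try(pracma::jacobian(f, unname(params)), silent = TRUE)
  if (inherits(J, "try-error") || !all(is.finite(J))) return(out)
  sse <- wsse(y, f(unname(params)), w)
  s2 <- sse / df
  JtWJ <- t(J) %*% (w * J)
  cov <- try(solve(JtWJ) * s2, silent = TRUE)
  if (inherits(cov, "try-error")) return(out)
  i <- match(shape_param, names(params))
  se <- sqrt(max(cov[i, i], 0))
  if (se == 0) {
    # perfect fit: the shape parameter is exactly identified
    tval <- if (params[[shape_param]] == 0) 0 else Inf
  } else {
    tval <- params[[shape_param]] / se
  }
  list(se = se, t = tval, p = 2 * stats::pt(-abs(tval), df))
}

#' Fit one response-model family by weighted least squares
#'
#' Fits a single family from [response_families] to dose-response data.
#' Linear and log families are solved in closed form; exponential and power
#' families profile their nonlinear rate parameter over a deterministic
#' sign-symmetric log-spaced grid with golden-section refinement; the
#' quadratic plateau profiles its join point the same way. Every fit is
#' therefore reproducible without random restarts.
#'
#' Model comparison uses the least-squares AIC
#' `n*log(SSE/n) + 2*(k + 1)` with `k` mean parameters. Significance of the
#' family's shape parameter (the slope `b`, or `a` for the log family) is
#' an asymptotic t-test using the covariance from the numerical Jacobian at
#' the optimum.
#'
#' A quadratic-plateau fit whose curvature comes out non-negative (no
#' interior maximum) falls back to the linear family with `optimum_n = 0`.
#'
#' @param data Data frame with columns `x` (dose, >= 0), `y` (response) and
#'   optionally `weights` (> 0).
#' @param family One of [response_families].
#' @param weights Optional weights vector, overriding `data$weights`.
#' @param alpha Significance level for the shape-parameter test
#'   (default 0.05).
#' @return A `response_fit` object: list with `family`, `params` (named),
#'   `sse`, `aic`, `n`, `significant`, `p_value`, `shape_param`,
#'   `optimum_n` (plateau only, else `NA`), `converged`, `fallback`.
#'   A failed fit returns `converged = FALSE` rather than an error.
#' @export
#' @examples
#' d <- data.frame(x = c(0, 28, 56, 84, 112, 140, 168, 196))
#' d$y <- 2 * exp(-0.01 * (d$x + 1))
#' fit_family(d, "exponential")
fit_family <- function(data, family = response_families, weights = NULL,
                       alpha = 0.05) {
  family <- match.arg(family)
  x <- data$x
  y <- data$y
  stopifnot(length(x) == length(y), all(x >= 0))
  w <- weights %||% data[["weights"]] %||% rep(1, length(y))
  stopifnot(all(w > 0), length(w) == length(y))
  n <- length(y)
  k <- if (family == "quad_plateau") 3L else 2L
  if (n < k + 2) {
    stop("need at least ", k + 2, " points for a ", k, "-parameter family",
         call. = FALSE)
  }

  failed <- function() {
    structure(list(family = family, params = NULL, sse = NA_real_,
                   aic = Inf, n = n, significant = FALSE,
                   p_value = NA_real_, shape_param = NA_character_,
                   optimum_n = NA_real_, converged = FALSE,
                   fallback = FALSE, weights = w, data = data),
              class = "response_fit")
  }

  core <- switch(
    family,
    linear = {
      fit <- stats::lm.wfit(cbind(1, x), y, w)
      co <- fit$coefficients
      list(params = c(a = unname(co[1]), b = unname(co[2])),
           sse = wsse(y, co[1] + co[2] * x, w), shape = "b")
    },
    log = {
      lx <- log(x + 1)
      fit <- stats::lm.wfit(cbind(1, lx), y, w)
      co <- fit$coefficients
      list(params = c(a = unname(co[2]), c = unname(co[1])),
           sse = wsse(y, co[1] + co[2] * lx, w), shape = "a")
    },
    exponential = {
      pf <- profile_fit(x, y, w, function(b, x) exp(b * (x + 1)),
                        signed_log_grid(1e-4, 1, 21))
      if (is.null(pf)) return(failed())
      list(params = c(a = pf$a, b = pf$b), sse = pf$sse, shape = "b")
    },
    power = {
      pf <- profile_fit(x, y, w, function(b, x) (x + 1)^b,
                        signed_log_grid(1e-3, 5, 25))
      if (is.null(pf)) return(failed())
      list(params = c(a = pf$a, b = pf$b), sse = pf$sse, shape = "b")
    },
    quad_plateau = {
      qp <- fit_quad_plateau(x, y, w)
      if (is.null(qp)) return(failed())
      if (is.na(qp$x0) || qp$c >= 0) {
        # no interior maximum: treat the response as linear, optimum 0
        lin <- fit_family(data, "linear", weights = w, alpha = alpha)
        lin$fallback <- TRUE
        lin$optimum_n <- 0
        return(lin)
      }
      list(params = c(a = qp$a, b = qp$b, c = qp$c), sse = qp$sse,
           shape = "b", x0 = qp$x0)
    }
  )
  if (inherits(core, "response_fit")) return(core)

  aic <- n * log(max(core$sse, .Machine$double.xmin) / n) + 2 * (k + 1)
  inference <- fit_param_inference(x, y, w, family, core$params, core$shape)
  optimum <- if (family == "quad_plateau") core$x0 else NA_real_
  structure(
    list(family = family, params = core$params, sse = core$sse, aic = aic,
         n = n,
         significant = is.finite(inference$p) && inference$p < alpha,
         p_value = inference$p, shape_se = inference$se,
         shape_param = core$shape, optimum_n = optimum,
         converged = TRUE, fallback = FALSE, weights = w, data = data),
    class = "response_fit"
  )
}

#' @export
print.response_fit <- function(x, ...) {
  if (!x$converged) {
    cat("response_fit (", x$family, "): fit failed\n", sep = "")
    return(invisible(x))
  }
  cat("response_fit: ", x$family,
      if (x$fallback) " (plateau fallback)" else "", "\n", sep = "")
  print(round(x$params, 6))
  cat(sprintf("n = %d, SSE = %.6g, AIC = %.3f, p(%s) = %.4g%s\n",
              x$n, x$sse, x$aic, x$shape_param, x$p_value,
              if (x$significant) " *" else ""))
  if (!is.na(x$optimum_n)) cat("optimum_n =", round(x$optimum_n, 3), "\n")
  invisible(x)
}

#' @export
predict.response_fit <- function(object, newdata = NULL, ...) {
  if (!object$converged) stop("cannot predict from a failed fit")
  x <- if (is.null(newdata)) object$data$x else
    (if (is.data.frame(newdata)) newdata$x else newdata)
  response_curve(object$family, object$params)(x)
}

#' Select the best significant response model
#'
#' Fits each candidate family and returns, among those whose shape
#' parameter differs from zero at level `alpha`, the one with the lowest
#' AIC. Returns `NULL` when no candidate is significant (no detectable
#' response to N addition) or when all fits failed. Exact AIC ties break
#' deterministically by the canonical family order
#' linear < log < power < exponential < quad_plateau.
#'
#' @inheritParams fit_family
#' @param candidates Character vector of families to try. The default
#'   covers the rate-response families (the plateau family is reserved for
#'   yield data via [optimal_n()]).
#' @return The winning `response_fit` (with all candidate fits attached as
#'   attribute `"fits"`), or `NULL` when no candidate is significant.
#' @export
select_model <- function(data, candidates = c("linear", "log", "power",
                                              "exponential"),
                         weights = NULL, alpha = 0.05) {
  stopifnot(length(candidates) >= 1, all(candidates %in% response_families))
  candidates <- response_families[response_families %in% candidates]
  fits <- lapply(candidates, function(fam) {
    tryCatch(fit_family(data, fam, weights = weights, alpha = alpha),
             error = function(e) NULL)
  })
  names(fits) <- candidates
  ok <- vapply(fits, function(f) {
    !is.null(f) && f$converged && isTRUE(f$significant)
  }, logical(1))
  if (!any(ok)) return(NULL)
  aics <- vapply(fits[ok], function(f) f$aic, numeric(1))
  # which.min is stable, so ties resolve by canonical candidate order
  best <- fits[ok][[which.min(aics)]]
  attr(best, "fits") <- fits
  best
}

#' Inverse-rank replicate weights
#'
#' Weighting policy for yield-response fits: within each dose level,
#' replicate observations are ranked by their absolute deviation from the
#' level median and weighted 1/rank, so the most central replicate at each
#' level carries full weight and outlying replicates are down-weighted.
#'
#' @param x Dose vector.
#' @param y Response vector.
#' @return Weights vector (same length), values `1, 1/2, 1/3, ...` within
#'   each level.
#' @export
inverse_rank_weights <- function(x, y) {
  stopifnot(length(x) == length(y))
  w <- numeric(length(y))
  for (lev in unique(x)) {
    i <- which(x == lev)
    r <- rank(abs(y[i] - stats::median(y[i])), ties.method = "first")
    w[i] <- 1 / r
  }
  w
}

#' Agronomic optimum N rate from yield data
#'
#' Fits a quadratic-plateau model to yield-vs-N data and returns the join
#' point: the minimum N addition achieving maximum biomass. By default,
#' replicates are weighted by [inverse_rank_weights()] (`policy =
#' "inverse_rank"`); `"uniform"` uses equal weights. The optimum is clamped
#' to the observed dose range; a response still rising at the highest dose
#' returns that dose with a boundary flag. When the plateau fit shows no
#' significant N effect the optimum is 0 (fertilizer indistinguishable from
#' none).
#'
#' @param data Data frame with `x` (N level) and `y` (yield).
#' @param policy Weighting policy, `"inverse_rank"` or `"uniform"`.
#' @param alpha Significance level for the N-effect test.
#' @return The optimum N rate (kg N ha-1 yr-1) with attributes `"fit"` (the
#'   `response_fit`) and `"boundary"` (logical).
#' @export
#' @examples
#' x <- rep(c(0, 28, 56, 84, 112, 140, 168, 196), each = 2)
#' f <- response_curve("quad_plateau", c(a = 2, b = 0.2, c = -0.001))
#' optimal_n(data.frame(x = x, y = f(x)))
optimal_n <- function(data, policy = c("inverse_rank", "uniform"),
                      alpha = 0.05) {
  policy <- match.arg(policy)
  stopifnot(length(unique(data$x)) >= 4)
  w <- if (policy == "inverse_rank") {
    inverse_rank_weights(data$x, data$y)
  } else {
    rep(1, nrow(data))
  }
  fit <- fit_family(data, "quad_plateau", weights = w, alpha = alpha)
  if (!fit$converged || !fit$significant) {
    out <- 0
    attr(out, "fit") <- fit
    attr(out, "boundary") <- FALSE
    return(out)
  }
  raw <- fit$optimum_n
  boundary <- raw > max(data$x)
  out <- min(max(raw, 0), max(data$x))
  attr(out, "fit") <- fit
  attr(out, "boundary") <- boundary
  out
}
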