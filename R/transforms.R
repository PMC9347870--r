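#' Growth rate implied by a reproduction number (gamma closed form)
#'
#' Under exponential growth and a gamma generation-time distribution with
#' shape `a` and rate `b`, the moment-generating-function relation
#' `R * M_w(-r) = 1` has the closed-form solution `r = b * (R^(1/a) - 1)`.
#' `R = 1` maps exactly to `r = 0`: the epidemic-threshold interpretations
#' of the two statistics coincide.
#'
#' @param R Reproduction number(s), > 0.
#' @param shape,rate Gamma shape (dimensionless) and rate (per day).
#' @return Growth rate(s) in per-day units.
#' @export
growth_from_R_gamma <- function(R, shape, rate) {
  if (any(R <= 0)) stop("`R` must be positive", call. = FALSE)
  if (shape <= 0 || rate <= 0) {
    stop("gamma `shape` and `rate` must be positive", call. = FALSE)
  }
  rate * (R^(1 / shape) - 1)
}

#' Reproduction number implied by a growth rate (gamma closed form)
#'
#' Exact inverse of [growth_from_R_gamma()]: `R = (1 + r/b)^a`, valid on the
#' MGF domain `r > -b`.
#'
#' @param r Growth rate(s), per day, with `r > -rate`.
#' @inheritParams growth_from_R_gamma
#' @return Reproduction number(s), > 0.
#' @export
R_from_growth_gamma <- function(r, shape, rate) {
  if (shape <= 0 || rate <= 0) {
    stop("gamma `shape` and `rate` must be positive", call. = FALSE)
  }
  if (any(r <= -rate)) {
    stop("`r` must exceed -rate (gamma MGF domain)", call. = FALSE)
  }
  (1 + r / rate)^shape
}

#' Growth rate implied by a reproduction number (numeric MGF root)
#'
#' Solves `R * M_w(-r) = 1` on the empirical moment generating function of a
#' discretized generation-time distribution by bracketed root finding.
#' `M_w(-r)` is strictly decreasing in `r`, so the root is unique; the
#' bracket is expanded geometrically from 0 and the root polished to 1e-12.
#'
#' @param R Reproduction number(s), > 0.
#' @param gt A [generation_time()] object.
#' @param r_limit Bracket expansion bound (per day); roots beyond it raise a
#'   convergence error, since far outside the data-supported range the
#'   discretized MGF is numerically unreliable.
#' @return Growth rate(s) in per-day units.
#' @export
growth_from_R_numeric <- function(R, gt, r_limit = 20) {
  stopifnot(inherits(gt, "generation_time"))
  if (any(R <= 0)) stop("`R` must be positive", call. = FALSE)
  solve_one <- function(Ri) {
    f <- function(r) Ri * gt_mgf(gt, -r) - 1
    f0 <- f(0)
    if (abs(f0) < 1e-14) return(0)
    # f is strictly decreasing in r; expand the bracket away from 0 on the
    # side containing the root
    bound <- if (f0 > 0) 0.05 else -0.05
    while (sign(f(bound)) == sign(f0)) {
      bound <- bound * 2
      if (abs(bound) > r_limit) {
        stop(sprintf(
          "no MGF root for R = %g within |r| <= %g per day", Ri, r_limit
        ), call. = FALSE)
      }
    }
    interval <- sort(c(0, bound))
    stats::uniroot(f, interval, tol = 1e-12)$root
  }
  vapply(R, solve_one, numeric(1))
}

#' Growth rate implied by a reproduction number (linearised SIR)
#'
#' Under a linearised Susceptible-Infectious-Recovered model the relation
#' collapses to `r = (R - 1) / E[w]` with `E[w]` the mean generation time.
#' This agrees with the gamma closed form to first order around `R = 1` and
#' diverges quadratically away from it.
#'
#' @param R Reproduction number(s), > 0.
#' @param mean_gt Mean generation time in days, > 0.
#' @return Growth rate(s) in per-day units.
#' @export
growth_from_R_sir <- function(R, mean_gt) {
  if (any(R <= 0)) stop("`R` must be positive", call. = FALSE)
  if (mean_gt <= 0) stop("`mean_gt` must be positive", call. = FALSE)
  (R - 1) / mean_gt
}

#' Specification of an R-to-growth-rate transform
#'
#' @param kind One of `"gamma_closed_form"`, `"numeric_mgf"`,
#'   `"sir_linear"`.
#' @param gt A [generation_time()] object. `numeric_mgf` uses its
#'   discretized probabilities; `gamma_closed_form` its gamma parameters;
#'   `sir_linear` only its mean.
#' @return A `transform_spec` object.
#' @export
transform_spec <- function(kind = c("gamma_closed_form", "numeric_mgf",
                                    "sir_linear"), gt) {
  kind <- match.arg(kind)
  stopifnot(inherits(gt, "generation_time"))
  if (kind == "gamma_closed_form" && (is.null(gt$shape) || is.null(gt$rate))) {
    stop("gamma_closed_form requires a gamma-parametrised generation time",
         call. = FALSE)
  }
  structure(list(kind = kind, gt = gt), class = "transform_spec")
}

apply_transform <- function(R, spec) {
  switch(spec$kind,
    gamma_closed_form = growth_from_R_gamma(R, spec$gt$shape, spec$gt$rate),
    numeric_mgf = growth_from_R_numeric(R, spec$gt),
    sir_linear = growth_from_R_sir(R, spec$gt$mean_days)
  )
}

#' Map an Rt posterior to a model-based growth-rate series
#'
#' Pushes the per-day posterior mean and equal-tailed credible bounds of
#' `R_t` through a monotone R-to-r transform, giving a growth-rate series
#' with credible intervals. Because every transform here is strictly
#' increasing, mapping the quantile bounds is exact for the interval (no
#' resampling needed), zero crossings of `r_t` coincide exactly with unit
#' crossings of `R_t`, and interval ordering is preserved.
#'
#' @param posterior An `rt_posterior` from [estimate_rt()].
#' @param spec A [transform_spec()].
#' @return A `growth_rate_series` with method tag `"model_transform"` and
#'   `ci_lower`/`ci_upper` filled in. Days where the transform is undefined
#'   are `NA`.
#' @export
transform_posterior <- function(posterior, spec) {
  stopifnot(inherits(posterior, "rt_posterior"),
            inherits(spec, "transform_spec"))
  safe <- function(R) {
    out <- rep(NA_real_, length(R))
    ok <- is.finite(R) & R > 0
    out[ok] <- apply_transform(R[ok], spec)
    out
  }
  s <- posterior$summary
  new_growth_rate_series(
    values = safe(s$mean_rt),
    method = "model_transform",
    ci_lower = safe(s$ci_lower),
    ci_upper = safe(s$ci_upper)
  )
}

#' Critical fraction of transmissions to block
#'
#' The smallest proportion `f` of current transmissions that must be
#' prevented for the epidemic to stop growing, i.e. the smallest `f` with
#' `(1 - f) * R <= 1`: `f = 1 - 1/R` for `R > 1` and 0 otherwise. At
#' `R = 2`, half of transmissions must be blocked.
#'
#' @param R Reproduction number(s), > 0.
#' @return Fraction(s) in `[0, 1)`.
#' @export
critical_prevention_fraction <- function(R) {
  if (any(R <= 0)) stop("`R` must be positive", call. = FALSE)
  pmax(0, 1 - 1 / R)
}
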