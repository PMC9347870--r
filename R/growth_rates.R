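#' Savitzky-Golay convolution coefficients
#'
#' Weights of the local least-squares polynomial fit over a centred window of
#' `window` days, evaluated at the window centre. With `deriv = 0` the filter
#' returns the smoothed value; with `deriv = 1` its first derivative (per
#' day). For `poly_order <= 1` and `deriv = 0` the weights reduce exactly to
#' the `1/m` moving average.
#'
#' @param window Odd window length `m` >= 3, in days.
#' @param poly_order Degree of the local polynomial, `0 <= poly_order < m`.
#' @param deriv Derivative order, 0 or 1, with `deriv <= poly_order`.
#' @return An `sg_filter` object with fields `window`, `poly_order`, `deriv`
#'   and `weights` (length `m`, indexed by offsets `-(m-1)/2 .. (m-1)/2`).
#' @examples
#' sg_coefficients(5, 1, 0)$weights # the 1/5 moving average
#' @export
sg_coefficients <- function(window, poly_order, deriv = 0) {
  if (window < 3 || window %% 2 == 0) {
    stop("invalid filter: `window` must be an odd integer >= 3", call. = FALSE)
  }
  if (poly_order < 0 || poly_order >= window) {
    stop("invalid filter: need 0 <= poly_order < window", call. = FALSE)
  }
  if (!deriv %in% c(0, 1) || deriv > poly_order) {
    stop("invalid filter: `deriv` must be 0 or 1 and <= poly_order",
         call. = FALSE)
  }
  half <- (window - 1) / 2
  offsets <- seq(-half, half)
  A <- outer(offsets, 0:poly_order, `^`)
  # pseudo-inverse row deriv+1 evaluated at the centre; factorial(deriv) = 1
  # for deriv in {0, 1}
  C <- solve(crossprod(A), t(A))
  structure(
    list(window = window, poly_order = poly_order, deriv = deriv,
         offsets = offsets, weights = C[deriv + 1, ]),
    class = "sg_filter"
  )
}

#' Apply a Savitzky-Golay filter to a series
#'
#' Discrete convolution of the series with the filter weights. The
#' `(window - 1) / 2` days at each end have no full window and are returned
#' as `NA` (no padding: padded edges would be a hidden modelling
#' assumption).
#'
#' @param x Numeric series, length >= `spec$window`.
#' @param spec An [sg_coefficients()] filter.
#' @return Numeric vector of `length(x)` with `NA` edges.
#' @export
sg_apply <- function(x, spec) {
  stopifnot(inherits(spec, "sg_filter"))
  m <- spec$window
  n <- length(x)
  if (n < m) {
    stop("series shorter than the filter window", call. = FALSE)
  }
  half <- (m - 1) / 2
  out <- rep(NA_real_, n)
  # embed() rows hold x[t], x[t-1], ..., x[t-m+1]; reversing the weights
  # lines them up with offsets +half .. -half around centre t - half
  X <- stats::embed(x, m)
  out[(half + 1):(n - half)] <- as.vector(X %*% rev(spec$weights))
  out
}

new_growth_rate_series <- function(values, method, lag_shift_days = 0L,
                                   ci_lower = NULL, ci_upper = NULL) {
  structure(
    list(values = values, method = method,
         lag_shift_days = as.integer(lag_shift_days),
         undefined_edges = sum(!is.finite(values)),
         ci_lower = ci_lower, ci_upper = ci_upper),
    class = "growth_rate_series"
  )
}

#' @export
print.growth_rate_series <- function(x, ...) {
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf(
    "Growth-rate series (%s): %d days, %d undefined, shift %+d d, range [%.4f, %.4f] /day\n",
    x$method, length(x$values), x$undefined_edges, x$lag_shift_days,
    rng[1], rng[2]
  ))
  invisible(x)
}

# Shift a series in time: positive = right (delay), negative = left
# (advance); vacated positions become NA.
shift_series <- function(x, shift) {
  n <- length(x)
  out <- rep(NA_real_, n)
  src <- seq_len(n) - shift
  ok <- src >= 1 & src <= n
  out[ok] <- x[src[ok]]
  out
}

#' Model-agnostic growth rate from the smoothed log incidence
#'
#' Two-stage estimator of `r_t = d log S[I_t] / dt`: first smooth the raw
#' counts with a derivative-0 Savitzky-Golay filter, floor the result at a
#' small positive constant, take logs, then apply the matching derivative-1
#' filter. The staging avoids taking logs of zero counts; days whose
#' smoothed incidence hit the floor are unreliable and should be screened by
#' an incidence threshold downstream.
#'
#' @param incidence Non-negative numeric vector of daily counts.
#' @param window,poly_order Savitzky-Golay window (odd, days) and polynomial
#'   order shared by both stages; defaults 15 and 2, roughly two mean
#'   generation times of a mean-8-day disease.
#' @param floor Lower bound applied to the smoothed counts before the log
#'   (default 0.5 cases).
#' @param shift_days Optional time shift applied to the finished series
#'   (positive = right/delay); used when comparing against model-based
#'   estimates, which this filter leads by about half a mean generation
#'   time.
#' @return A `growth_rate_series` with method tag `"sg_log_incidence"`. No
#'   credible intervals are attached: the estimator is a deterministic
#'   filter.
#' @export
growth_from_log_incidence <- function(incidence, window = 15, poly_order = 2,
                                      floor = 0.5, shift_days = 0) {
  if (any(incidence < 0, na.rm = TRUE)) {
    stop("incidence must be non-negative", call. = FALSE)
  }
  smooth_spec <- sg_coefficients(window, poly_order, 0)
  deriv_spec <- sg_coefficients(window, max(poly_order, 1), 1)
  smoothed <- sg_apply(incidence, smooth_spec)
  log_s <- log(pmax(smoothed, floor))
  r <- sg_apply(log_s, deriv_spec)
  # a floored (effectively zero) smoothed count means the log-derivative is
  # undefined there, not zero
  r[is.finite(smoothed) & smoothed < floor] <- NA_real_
  new_growth_rate_series(shift_series(r, shift_days), "sg_log_incidence",
                         lag_shift_days = shift_days)
}

#' Growth rate from the total infectiousness as an implicit filter
#'
#' The total infectiousness `Lambda_t` is itself a weighted moving average
#' of past incidence — an epidemiologically informed smoothing kernel — so a
#' single derivative-1 Savitzky-Golay pass over `log Lambda_t` yields a
#' growth-rate estimate without any further smoothing stage. Because the
#' generation-time kernel looks backwards, the raw series lags the epidemic
#' by about the mean generation time; by default it is advanced (left
#' shifted) by half that mean so that it aligns with model-based estimates.
#'
#' @inheritParams growth_from_log_incidence
#' @param gt A daily [generation_time()] object.
#' @param shift_days Time shift applied to the finished series; default
#'   `-round(mean/2)` (advance by half the mean generation time). Use 0 for
#'   the unshifted series, e.g. when measuring the lag itself with
#'   [align_lag()].
#' @return A `growth_rate_series` with method tag
#'   `"sg_total_infectiousness"` and the applied shift recorded.
#' @export
growth_from_total_infectiousness <- function(incidence, gt, window = 15,
                                             poly_order = 2, floor = 0.5,
                                             shift_days = NULL) {
  if (any(incidence < 0, na.rm = TRUE)) {
    stop("incidence must be non-negative", call. = FALSE)
  }
  if (is.null(shift_days)) shift_days <- -round(gt$mean_days / 2)
  lam <- lambda_series(incidence, gt)[seq_along(incidence)]
  lam[1] <- NA_real_
  deriv_spec <- sg_coefficients(window, max(poly_order, 1), 1)
  log_lam <- log(pmax(lam, floor))
  r <- sg_apply(log_lam, deriv_spec)
  r[is.finite(lam) & lam < floor] <- NA_real_
  new_growth_rate_series(shift_series(r, shift_days),
                         "sg_total_infectiousness",
                         lag_shift_days = shift_days)
}

#' Lag between two growth-rate series by correlation matching
#'
#' Finds the integer shift `k` in `[-max_lag, max_lag]` maximising the
#' Pearson correlation between `a[t + k]` and `b[t]` over their defined
#' overlap; ties break toward the smaller `|k|`. A positive lag means
#' `series_a` is delayed relative to `series_b` by `k` days (it must be
#' advanced by `k` to match). Applied to the unshifted total-infectiousness
#' estimator against the smoothed-incidence one, the recovered lag
#' approximates the mean generation time.
#'
#' @param series_a,series_b `growth_rate_series` objects or plain numeric
#'   vectors on the same daily time axis.
#' @param max_lag Largest shift considered, in days.
#' @return Integer lag in days.
#' @export
align_lag <- function(series_a, series_b, max_lag = 15) {
  a <- if (inherits(series_a, "growth_rate_series")) series_a$values else series_a
  b <- if (inherits(series_b, "growth_rate_series")) series_b$values else series_b
  n <- min(length(a), length(b))
  a <- a[seq_len(n)]
  b <- b[seq_len(n)]
  overlap0 <- sum(is.finite(a) & is.finite(b))
  if (overlap0 < 3 * max_lag) {
    stop("insufficient overlap between the series for lag estimation",
         call. = FALSE)
  }
  lags <- seq(-max_lag, max_lag)
  cors <- vapply(lags, function(k) {
    ak <- shift_series(a, -k) # a advanced by k
    ok <- is.finite(ak) & is.finite(b)
    if (sum(ok) < 3 || stats::sd(ak[ok]) == 0 || stats::sd(b[ok]) == 0) {
      return(-Inf)
    }
    stats::cor(ak[ok], b[ok])
  }, numeric(1))
  best <- max(cors)
  candidates <- lags[cors >= best - 1e-12]
  candidates[which.min(abs(candidates))]
}
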