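#' Grid of candidate reproduction numbers
#'
#' @param min_r,max_r Grid range (strictly positive).
#' @param n Number of points (>= 50).
#' @return Object of class `rt_grid`: a strictly increasing numeric vector
#'   with a `resolution` attribute.
#' @export
rt_grid <- function(min_r = 0.01, max_r = 10, n = 2000) {
  if (min_r <= 0 || max_r <= min_r) {
    stop("grid bounds must satisfy 0 < min_r < max_r", call. = FALSE)
  }
  if (n < 50) stop("the R grid needs at least 50 points", call. = FALSE)
  values <- seq(min_r, max_r, length.out = n)
  structure(values, resolution = values[2] - values[1], class = "rt_grid")
}

# Row-stochastic transition matrix of the random walk on the R grid:
# from grid point R the next state is Gaussian with mean R and standard
# deviation eta * sqrt(R), projected back onto the grid.
state_transition_matrix <- function(grid, eta) {
  g <- as.numeric(grid)
  n <- length(g)
  sd <- eta * sqrt(g)
  P <- stats::dnorm(matrix(g, n, n, byrow = TRUE), mean = g, sd = sd)
  P / rowSums(P)
}

#' Forward Bayesian filter for the instantaneous reproduction number
#'
#' Grid-based recursive filter in the style of EpiFilter: the hidden state
#' `R_t` follows a Gaussian random walk with standard deviation
#' `eta * sqrt(R_{t-1})`, and observations are Poisson counts with mean
#' `Lambda_t * R_t`. Starting from a uniform prior over the grid, each day is
#' a predict step (propagation through the state kernel) followed by a
#' correct step (multiplication by the Poisson likelihood, in log domain,
#' then renormalisation).
#'
#' @param incidence Non-negative integer vector (length >= 3).
#' @param gt A daily [generation_time()] object.
#' @param grid An [rt_grid()].
#' @param eta State-noise scale in (0, 1].
#' @return List with `filtered` (T x n matrix of per-day posteriors; day 1 is
#'   the prior), `predictive` (T x n matrix of one-step-ahead state
#'   distributions, before seeing the day's count), `grid`, `eta`, and
#'   `lambda` (the `Lambda_t` series of length T + 1).
#' @export
filter_forward <- function(incidence, gt, grid = rt_grid(), eta = 0.1) {
  if (length(incidence) < 3) {
    stop("need at least 3 days of incidence", call. = FALSE)
  }
  if (eta <= 0 || eta > 1) stop("`eta` must lie in (0, 1]", call. = FALSE)
  g <- as.numeric(grid)
  n <- length(g)
  horizon <- length(incidence)
  P <- state_transition_matrix(grid, eta)
  lam <- lambda_series(incidence, gt)

  filt <- matrix(NA_real_, horizon, n)
  pred <- matrix(NA_real_, horizon, n)
  filt[1, ] <- rep(1 / n, n)
  for (t in 2:horizon) {
    prior_t <- as.vector(crossprod(P, filt[t - 1, ]))
    pred[t, ] <- prior_t
    if (lam[t] == 0 && incidence[t] > 0) {
      stop(sprintf(
        "impossible observation: %d cases on day %d with zero total infectiousness",
        incidence[t], t
      ), call. = FALSE)
    }
    loglik <- stats::dpois(incidence[t], lam[t] * g, log = TRUE)
    loglik[!is.finite(loglik)] <- -700
    post <- prior_t * exp(loglik - max(loglik))
    total <- sum(post)
    if (total <= 0 || !is.finite(total)) {
      stop(sprintf("numerical underflow in the filter at day %d", t),
           call. = FALSE)
    }
    filt[t, ] <- post / total
  }
  list(filtered = filt, predictive = pred, grid = grid, eta = eta,
       lambda = lam, transition = P)
}

#' Fixed-interval backward smoother over the filtered distributions
#'
#' Combines each day's filtered posterior with the following day's smoothed
#' posterior through the same random-walk state kernel, so every day's
#' estimate uses the whole incidence curve. The final day's smoothed
#' distribution equals its filtered one. Predicted probabilities in the
#' backward ratio are floored at a tiny positive constant to guard against
#' division by zero.
#'
#' @param forward Output of [filter_forward()].
#' @return T x n matrix of smoothed per-day posteriors.
#' @export
smooth_backward <- function(forward) {
  filt <- forward$filtered
  P <- forward$transition
  if (is.null(P)) P <- state_transition_matrix(forward$grid, forward$eta)
  horizon <- nrow(filt)
  smo <- filt
  for (t in (horizon - 1):1) {
    pred_next <- as.vector(crossprod(P, filt[t, ]))
    ratio <- smo[t + 1, ] / pmax(pred_next, 1e-300)
    row <- filt[t, ] * as.vector(P %*% ratio)
    smo[t, ] <- row / sum(row)
  }
  smo
}

# Equal-tailed interval of a Poisson mixture sum_i w_i Pois(mu_i), found by
# bisection on the mixture CDF.
poisson_mixture_interval <- function(weights, means, level = 0.95) {
  keep <- weights > 1e-12
  w <- weights[keep] / sum(weights[keep])
  mu <- means[keep]
  mix_cdf <- function(k) sum(w * stats::ppois(k, mu))
  qmix <- function(p) {
    lo <- 0
    hi <- max(stats::qpois(min(1 - 1e-12, p + (1 - p) / 2), max(mu)), 1)
    while (mix_cdf(hi) < p) hi <- hi * 2 + 1
    while (lo < hi) {
      mid <- floor((lo + hi) / 2)
      if (mix_cdf(mid) >= p) hi <- mid else lo <- mid + 1
    }
    lo
  }
  alpha <- (1 - level) / 2
  c(lower = qmix(alpha), upper = qmix(1 - alpha))
}

# Equal-tailed quantiles of a discrete distribution over the grid.
grid_quantiles <- function(prob_row, grid, probs = c(0.025, 0.975)) {
  cdf <- cumsum(prob_row)
  vapply(probs, function(p) grid[which(cdf >= p)[1]], numeric(1))
}

#' Estimate the instantaneous reproduction number from an incidence curve
#'
#' Runs the forward filter and backward smoother over an R grid and
#' summarises the result. The headline estimate `mean_rt` is the posterior
#' mean under the smoothed distributions (the minimum-mean-squared-error
#' choice); credible bounds are equal-tailed 2.5%/97.5% posterior quantiles.
#' One-step-ahead predictions of the incidence itself come from the filtered
#' side: the day-`t` predictive distribution of `R` (before observing
#' `I_t`) mixed with the Poisson observation model gives the predictive mean
#' `sum_R P(R) * Lambda_t * R` and an equal-tailed 95% prediction interval.
#' Comparing these predictions with the observed counts validates the fitted
#' model.
#'
#' @inheritParams filter_forward
#' @param compute_prediction If `FALSE`, skip the one-step-ahead prediction
#'   intervals (the slowest summary) and return `NA` columns for them.
#' @return An `rt_posterior` object: list with `grid`, `eta`, `filtered` and
#'   `smoothed` matrices, and a `summary` data frame with columns `day`,
#'   `incidence`, `mean_rt`, `ci_lower`, `ci_upper`, `pred_mean`,
#'   `pred_lower`, `pred_upper`. Day 1 reports the prior.
#' @export
estimate_rt <- function(incidence, gt, grid = rt_grid(), eta = 0.1,
                        compute_prediction = TRUE) {
  fwd <- filter_forward(incidence, gt, grid = grid, eta = eta)
  smo <- smooth_backward(fwd)
  g <- as.numeric(grid)
  horizon <- length(incidence)

  mean_rt <- as.vector(smo %*% g)
  ci <- t(apply(smo, 1, grid_quantiles, grid = g))

  pred_mean <- rep(NA_real_, horizon)
  pred_lo <- rep(NA_real_, horizon)
  pred_hi <- rep(NA_real_, horizon)
  for (t in 2:horizon) {
    mu <- fwd$lambda[t] * g
    pred_mean[t] <- sum(fwd$predictive[t, ] * mu)
    if (compute_prediction && fwd$lambda[t] > 0) {
      pi <- poisson_mixture_interval(fwd$predictive[t, ], mu)
      pred_lo[t] <- pi[["lower"]]
      pred_hi[t] <- pi[["upper"]]
    }
  }

  structure(
    list(
      grid = grid,
      eta = eta,
      filtered = fwd$filtered,
      smoothed = smo,
      lambda = fwd$lambda,
      summary = data.frame(
        day = seq_len(horizon),
        incidence = incidence,
        mean_rt = mean_rt,
        ci_lower = ci[, 1],
        ci_upper = ci[, 2],
        pred_mean = pred_mean,
        pred_lower = pred_lo,
        pred_upper = pred_hi
      )
    ),
    class = "rt_posterior"
  )
}

#' @export
print.rt_posterior <- function(x, ...) {
  s <- x$summary
  last <- s[nrow(s), ]
  cat(sprintf(
    "Rt posterior over %d days (grid of %d points in [%.2f, %.2f], eta = %g)\n  final-day smoothed R: %.2f (95%% CrI %.2f-%.2f)\n",
    nrow(s), length(as.numeric(x$grid)), min(as.numeric(x$grid)),
    max(as.numeric(x$grid)), x$eta, last$mean_rt, last$ci_lower, last$ci_upper
  ))
  invisible(x)
}

#' Write the per-day posterior summary as CSV
#'
#' @param posterior An `rt_posterior`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_rt_summary <- function(posterior, path) {
  stopifnot(inherits(posterior, "rt_posterior"))
  utils::write.csv(posterior$summary, path, row.names = FALSE)
  invisible(path)
}
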