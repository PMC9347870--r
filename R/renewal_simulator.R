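#' Sinusoidal profile of the true reproduction number
#'
#' `R_t = baseline + amplitude * sin(2 * pi * t / period)` for
#' `t = 1, ..., horizon`, emulating seasonally forced transmission with
#' alternating growing and declining seasons.
#'
#' @param horizon Number of days `T` (>= 2).
#' @param baseline Mean level of `R_t` (dimensionless).
#' @param amplitude Seasonal amplitude; must satisfy
#'   `baseline - |amplitude| > 0` so the profile stays positive.
#' @param period Season length in days.
#' @return Numeric vector of length `horizon`, strictly positive.
#' @export
seasonal_rt_profile <- function(horizon, baseline = 1, amplitude = 0.75,
                                period = 120) {
  if (!is.numeric(horizon) || horizon < 2) {
    stop("`horizon` must be at least 2 days", call. = FALSE)
  }
  if (period <= 0) stop("`period` must be positive", call. = FALSE)
  if (baseline - abs(amplitude) <= 0) {
    stop("invalid profile: baseline - |amplitude| must exceed 0 so R_t > 0",
         call. = FALSE)
  }
  t <- seq_len(horizon)
  baseline + amplitude * sin(2 * pi * t / period)
}

#' Total infectiousness of past incidence
#'
#' The renewal model's effective "infectious pressure" at day `t`:
#' `Lambda_t = sum_{j=1}^{min(t-1, L)} I_{t-j} * w_j`, the convolution of the
#' incidence curve with the generation-time distribution. It is both the
#' expected-case multiplier in `E[I_t] = Lambda_t * R_t` and, viewed as a
#' moving weighted average, an implicit smoothing filter of the incidence.
#'
#' @param incidence Non-negative integer vector `I_1..I_T`.
#' @param gt A daily [generation_time()] object.
#' @param t Day at which to evaluate, `2 <= t <= T + 1` (`T + 1` gives the
#'   next-day value used for one-step-ahead prediction).
#' @return A single non-negative number.
#' @seealso [lambda_series()] for the whole curve at once.
#' @export
total_infectiousness <- function(incidence, gt, t) {
  stopifnot(inherits(gt, "generation_time"))
  if (gt$step != 1) {
    stop("the renewal convolution requires a daily generation time (step = 1)",
         call. = FALSE)
  }
  if (t < 2) {
    stop("total infectiousness is undefined before day 2 (no past incidence)",
         call. = FALSE)
  }
  if (t > length(incidence) + 1) {
    stop("`t` may exceed the incidence length by at most 1", call. = FALSE)
  }
  jmax <- min(t - 1, length(gt$probs))
  j <- seq_len(jmax)
  sum(incidence[t - j] * gt$probs[j])
}

#' Total infectiousness for every day of an incidence curve
#'
#' @inheritParams total_infectiousness
#' @return Numeric vector of length `length(incidence) + 1`; element `t` is
#'   `Lambda_t`, with `Lambda_1 = 0` (no past incidence) and the final
#'   element the next-day value used for prediction.
#' @export
lambda_series <- function(incidence, gt) {
  stopifnot(inherits(gt, "generation_time"))
  if (gt$step != 1) {
    stop("the renewal convolution requires a daily generation time (step = 1)",
         call. = FALSE)
  }
  n <- length(incidence)
  w <- gt$probs
  lam <- numeric(n + 1)
  for (t in 2:(n + 1)) {
    jmax <- min(t - 1, length(w))
    j <- seq_len(jmax)
    lam[t] <- sum(incidence[t - j] * w[j])
  }
  lam
}

#' Simulate an epidemic from the renewal model
#'
#' Generates daily incidence under `E[I_t] = Lambda_t * R_t` with Poisson
#' (default) or negative-binomial observation noise. The first
#' `seed_days` days are constant imports of `seed_cases` so that the total
#' infectiousness is well defined before endogenous transmission takes over.
#'
#' @param profile Strictly positive numeric vector of true `R_t` values,
#'   e.g. from [seasonal_rt_profile()].
#' @param gt A daily [generation_time()] object.
#' @param seed_cases Imported cases per seeding day (>= 1).
#' @param rng_seed Integer seed; identical seeds give identical trajectories.
#' @param seed_days Length of the import period; default
#'   `max(7, round(L / 2))` with `L` the generation-time support.
#' @param deterministic If `TRUE`, propagate means instead of sampling
#'   (useful for analytic checks; incidence is then real-valued).
#' @param dispersion Negative-binomial size parameter `k`; `Inf` (default)
#'   gives Poisson noise.
#' @return An `epidemic_trajectory` object: a list with `incidence`,
#'   `total_infectiousness` (`Lambda_t`, length `T`), `true_rt` (the profile),
#'   `seed`, `seed_days` and an `extinct` flag set when the final
#'   generation-time window has no cases. Extinction is not an error.
#' @export
simulate_renewal <- function(profile, gt, seed_cases = 50, rng_seed = 1,
                             seed_days = NULL, deterministic = FALSE,
                             dispersion = Inf) {
  stopifnot(inherits(gt, "generation_time"))
  if (any(!is.finite(profile)) || any(profile <= 0)) {
    stop("`profile` must be finite and strictly positive", call. = FALSE)
  }
  if (seed_cases < 1) stop("`seed_cases` must be at least 1", call. = FALSE)
  horizon <- length(profile)
  L <- length(gt$probs)
  if (is.null(seed_days)) seed_days <- max(7, round(L / 2))
  seed_days <- min(seed_days, horizon)
  if (!deterministic) set.seed(rng_seed)

  w <- gt$probs
  inc <- numeric(horizon)
  lam <- numeric(horizon)
  inc[seq_len(seed_days)] <- seed_cases
  for (t in 2:horizon) {
    jmax <- min(t - 1, L)
    j <- seq_len(jmax)
    lam[t] <- sum(inc[t - j] * w[j])
    if (t > seed_days) {
      mu <- lam[t] * profile[t]
      inc[t] <- if (deterministic) {
        mu
      } else if (is.finite(dispersion)) {
        stats::rnbinom(1, size = dispersion, mu = mu)
      } else {
        stats::rpois(1, mu)
      }
    }
  }
  tail_window <- max(horizon - L + 1, 1):horizon
  structure(
    list(
      incidence = inc,
      total_infectiousness = lam,
      true_rt = profile,
      generation_time = gt,
      seed = rng_seed,
      seed_days = seed_days,
      deterministic = deterministic,
      extinct = sum(inc[tail_window]) == 0
    ),
    class = "epidemic_trajectory"
  )
}

#' @export
print.epidemic_trajectory <- function(x, ...) {
  cat(sprintf(
    "Renewal-model epidemic: %d days, %s cases total%s\n  seed %d, %d seeding day(s), true R_t in [%.2f, %.2f]\n",
    length(x$incidence), format(sum(x$incidence), big.mark = ","),
    if (x$extinct) " (extinct)" else "", x$seed, x$seed_days,
    min(x$true_rt), max(x$true_rt)
  ))
  invisible(x)
}

#' Write / read a simulated trajectory as CSV (+ JSON side-car metadata)
#'
#' Columns: `day`, `incidence`, `true_R`, `total_infectiousness`. Metadata
#' (seed, seeding convention, extinction flag) goes to `<path>.json`.
#'
#' @param trajectory An `epidemic_trajectory`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "epidemic_trajectory"))
  tab <- data.frame(
    day = seq_along(trajectory$incidence),
    incidence = trajectory$incidence,
    true_R = trajectory$true_rt,
    total_infectiousness = trajectory$total_infectiousness
  )
  utils::write.csv(tab, path, row.names = FALSE)
  meta <- list(
    seed = trajectory$seed,
    seed_days = trajectory$seed_days,
    deterministic = trajectory$deterministic,
    extinct = trajectory$extinct
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read an incidence CSV (columns day, incidence)
#'
#' @param path CSV path; the first two columns are used.
#' @return Integer vector of daily incidence ordered by day.
#' @export
read_incidence <- function(path) {
  tab <- utils::read.csv(path)
  if (ncol(tab) < 2) stop("incidence CSV needs day and count columns",
                          call. = FALSE)
  tab <- tab[order(tab[[1]]), ]
  inc <- tab[[2]]
  if (anyNA(inc) || any(inc < 0)) {
    stop("incidence must be non-negative and free of NA", call. = FALSE)
  }
  inc
}
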