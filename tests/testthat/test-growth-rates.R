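test_that("both model-agnostic estimators are exact on exponentials", {
  gt <- default_gt()
  for (r in c(0.05, -0.05)) {
    t <- 1:120
    inc <- 500 * exp(r * t)
    interior <- 60:100
    g_inc <- growth_from_log_incidence(inc)
    expect_lt(max(abs(g_inc$values[interior] - r)), 1e-6)
    g_lam <- growth_from_total_infectiousness(inc, gt, shift_days = 0)
    expect_lt(max(abs(g_lam$values[interior] - r)), 1e-6)
    # the implicit-filter identity: I_t / Lambda_t = 1 / M(-r)
    lam <- lambda_series(inc, gt)[t]
    expect_lt(max(abs(inc[interior] / lam[interior] - 1 / gt_mgf(gt, -r))),
              1e-6)
  }
})

test_that("constant incidence gives zero growth and flagged edges", {
  inc <- rep(200, 60)
  g <- growth_from_log_incidence(inc, window = 15)
  defined <- which(is.finite(g$values))
  expect_equal(defined, 15:46)
  expect_equal(g$values[defined], rep(0, length(defined)), tolerance = 1e-12)
  expect_identical(g$method, "sg_log_incidence")
  expect_identical(g$lag_shift_days, 0L)

  # Lambda needs the full generation-time support (~37 days) of constant
  # incidence before it saturates; only then is its log-derivative zero
  inc_long <- rep(200, 120)
  g2 <- growth_from_total_infectiousness(inc_long, default_gt())
  expect_identical(g2$method, "sg_total_infectiousness")
  expect_identical(g2$lag_shift_days, -4L)
  expect_equal(g2$values[60:100], rep(0, 41), tolerance = 1e-10)

  expect_error(growth_from_log_incidence(c(-1, 2, 3)), "non-negative")
})

test_that("all-zero incidence yields undefined values, not an error", {
  g <- growth_from_log_incidence(rep(0, 40))
  expect_true(all(!is.finite(g$values) | g$values == 0))
})

test_that("filter-based growth rates track the model-based estimate", {
  fix <- seasonal_fixture()
  r_model <- transform_posterior(
    fix$posterior, transform_spec("gamma_closed_form", fix$gt)
  )
  half <- round(fix$gt$mean_days / 2)
  r_inc <- growth_from_log_incidence(fix$traj$incidence, shift_days = half)
  r_lam <- growth_from_total_infectiousness(fix$traj$incidence, fix$gt)
  for (r_sg in list(r_inc, r_lam)) {
    ok <- fix$traj$incidence > 10 & is.finite(r_model$values) &
      is.finite(r_sg$values)
    expect_gt(stats::cor(r_model$values[ok], r_sg$values[ok]), 0.8)
  }
})

test_that("align_lag recovers constructed shifts exactly", {
  set.seed(5)
  base <- sin(seq(0, 6 * pi, length.out = 200)) + rnorm(200, sd = 0.05)
  expect_identical(align_lag(base, base, max_lag = 10), 0L)
  for (k in c(3L, 8L, -5L)) {
    delayed <- rep(NA_real_, 200)
    src <- seq_len(200) - k
    ok <- src >= 1 & src <= 200
    delayed[ok] <- base[src[ok]]
    expect_identical(align_lag(delayed, base, max_lag = 12), k)
  }
  expect_error(align_lag(base[1:20], base[1:20], max_lag = 10),
               "insufficient overlap")
})

test_that("the lag between the two estimators approximates the mean generation time", {
  for (mean_gt in c(5, 8, 12)) {
    gt <- discretize_gamma(3, 3 / mean_gt)
    traj <- simulate_renewal(seasonal_rt_profile(300), gt, seed_cases = 50,
                             rng_seed = 7)
    a <- growth_from_total_infectiousness(traj$incidence, gt, shift_days = 0)
    b <- growth_from_log_incidence(traj$incidence)
    lag <- align_lag(a, b, max_lag = ceiling(2 * gt$mean_days))
    expect_lte(abs(lag - round(gt$mean_days)), 2)
  }
})

test_that("half-mean shifts bring the two estimators into agreement", {
  fix <- seasonal_fixture()
  inc <- fix$traj$incidence
  half <- round(fix$gt$mean_days / 2)
  r_inc_shifted <- growth_from_log_incidence(inc, shift_days = half)
  r_inc_raw <- growth_from_log_incidence(inc)
  r_lam_shifted <- growth_from_total_infectiousness(inc, fix$gt)
  r_lam_raw <- growth_from_total_infectiousness(inc, fix$gt, shift_days = 0)
  mad_between <- function(a, b) {
    ok <- inc > 10 & is.finite(a$values) & is.finite(b$values)
    stats::median(abs(a$values[ok] - b$values[ok]))
  }
  expect_lt(mad_between(r_lam_shifted, r_inc_shifted),
            mad_between(r_lam_raw, r_inc_raw))
})

test_that("the total-infectiousness filter overshoots less at troughs", {
  gt <- default_gt()
  half <- round(gt$mean_days / 2)
  overshoot <- vapply(1:5, function(s) {
    inc <- simulate_renewal(seasonal_rt_profile(300), gt, seed_cases = 50,
                            rng_seed = s)$incidence
    trough <- which(inc <= stats::quantile(inc, 0.15))
    peak_abs <- function(series) {
      vals <- series$values[intersect(trough, which(is.finite(series$values)))]
      max(abs(vals))
    }
    c(log_inc = peak_abs(growth_from_log_incidence(inc, shift_days = half)),
      lambda = peak_abs(growth_from_total_infectiousness(inc, gt)))
  }, numeric(2))
  expect_lt(mean(overshoot["lambda", ]), mean(overshoot["log_inc", ]))
})

test_that("the shifted total infectiousness approximates the smoothed incidence", {
  fix <- seasonal_fixture()
  inc <- fix$traj$incidence
  lam <- lambda_series(inc, fix$gt)[seq_along(inc)]
  S <- sg_apply(inc, sg_coefficients(15, 2, 0))
  shifted <- rep(NA_real_, length(lam))
  tau <- round(fix$gt$mean_days)
  shifted[seq_len(length(lam) - tau)] <- lam[(tau + 1):length(lam)]
  ok <- is.finite(S) & is.finite(shifted) & inc > 10
  rel_rms <- sqrt(mean((shifted[ok] - S[ok])^2)) / sqrt(mean(S[ok]^2))
  expect_lt(rel_rms, 0.15)
})
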