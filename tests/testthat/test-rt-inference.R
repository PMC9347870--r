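test_that("filtered and smoothed distributions are proper probabilities", {
  fix <- seasonal_fixture()
  post <- fix$posterior
  expect_equal(rowSums(post$filtered), rep(1, 300), tolerance = 1e-9)
  expect_equal(rowSums(post$smoothed), rep(1, 300), tolerance = 1e-9)
  expect_true(all(post$filtered >= 0))
  # boundary condition of the backward recursion
  expect_equal(post$smoothed[300, ], post$filtered[300, ])
  s <- post$summary
  expect_true(all(s$ci_lower <= s$mean_rt & s$mean_rt <= s$ci_upper))
})

test_that("smoothing does not inflate posterior variance", {
  post <- seasonal_fixture()$posterior
  g <- as.numeric(post$grid)
  moment_var <- function(m) as.vector(m %*% (g^2)) - as.vector(m %*% g)^2
  expect_lt(mean(moment_var(post$smoothed)), mean(moment_var(post$filtered)))
})

test_that("a constant-R epidemic is recovered within 10%", {
  gt <- default_gt()
  traj <- simulate_renewal(rep(2, 200), gt, seed_cases = 10, rng_seed = 3)
  fwd <- filter_forward(traj$incidence, gt, grid = test_grid(800, max_r = 4))
  final_mean <- sum(as.numeric(fwd$grid) * fwd$filtered[200, ])
  expect_lt(abs(final_mean - 2) / 2, 0.1)
})

test_that("smoothing reduces mean squared error against the truth", {
  gt <- default_gt()
  grid <- test_grid(400, max_r = 4)
  g <- as.numeric(grid)
  improved <- vapply(1:40, function(s) {
    traj <- simulate_renewal(rep(1.5, 100), gt, seed_cases = 10, rng_seed = s)
    fwd <- filter_forward(traj$incidence, gt, grid = grid)
    smo <- smooth_backward(fwd)
    days <- (traj$seed_days + 1):100
    mse_f <- mean((as.vector(fwd$filtered %*% g)[days] - 1.5)^2)
    mse_s <- mean((as.vector(smo %*% g)[days] - 1.5)^2)
    mse_s < mse_f
  }, logical(1))
  expect_gt(mean(improved), 0.8)
})

test_that("zero incidence with zero infectiousness carries no information", {
  gt <- default_gt()
  fwd <- filter_forward(rep(0L, 10), gt, grid = test_grid(200))
  # flat likelihood: the posterior equals the propagated prior every day
  for (t in 2:10) expect_equal(fwd$filtered[t, ], fwd$predictive[t, ])
})

test_that("cases appearing with zero total infectiousness are impossible", {
  gt <- default_gt()
  expect_error(filter_forward(c(0L, 5L, 1L), gt, grid = test_grid(200)),
               "impossible observation")
  expect_error(filter_forward(c(1L, 1L), gt, grid = test_grid(200)),
               "at least 3")
  expect_error(filter_forward(rep(1L, 5), gt, grid = test_grid(200), eta = 0),
               "eta")
  expect_error(rt_grid(0.1, 2, n = 10), "at least 50")
  expect_error(rt_grid(-1, 2), "0 < min_r")
})

test_that("ten-fold larger incidence sharpens the posterior", {
  gt <- default_gt()
  traj <- simulate_renewal(seasonal_rt_profile(150), gt, seed_cases = 20,
                           rng_seed = 9)
  grid <- test_grid(500)
  g <- as.numeric(grid)
  post_var <- function(inc) {
    smo <- smooth_backward(filter_forward(inc, gt, grid = grid))
    v <- as.vector(smo %*% (g^2)) - as.vector(smo %*% g)^2
    mean(v[-(1:20)])
  }
  expect_lt(post_var(traj$incidence * 10L), post_var(traj$incidence))
})

test_that("estimates are stable under grid refinement", {
  gt <- default_gt()
  traj <- simulate_renewal(seasonal_rt_profile(200), gt, seed_cases = 50,
                           rng_seed = 3)
  coarse <- estimate_rt(traj$incidence, gt, grid = rt_grid(0.01, 10, 1000),
                        compute_prediction = FALSE)$summary$mean_rt
  fine <- estimate_rt(traj$incidence, gt, grid = rt_grid(0.01, 10, 2000),
                      compute_prediction = FALSE)$summary$mean_rt
  expect_lt(max(abs(fine - coarse) / coarse), 0.01)
})

test_that("a steady-state epidemic is estimated near R = 1", {
  gt <- default_gt()
  traj <- simulate_renewal(rep(1, 150), gt, seed_cases = 100,
                           deterministic = TRUE)
  post <- estimate_rt(round(traj$incidence), gt, grid = test_grid(500),
                      compute_prediction = FALSE)
  burned <- post$summary$mean_rt[40:150]
  expect_true(all(burned > 0.9 & burned < 1.1))
})

test_that("one-step-ahead predictions cover the observed counts", {
  gt <- default_gt()
  traj <- simulate_renewal(seasonal_rt_profile(200), gt, seed_cases = 50,
                           rng_seed = 4)
  post <- estimate_rt(traj$incidence, gt, grid = test_grid(500))
  s <- post$summary
  ok <- is.finite(s$pred_lower)
  expect_gt(sum(ok), 150)
  covered <- s$incidence[ok] >= s$pred_lower[ok] &
    s$incidence[ok] <= s$pred_upper[ok]
  expect_gt(mean(covered), 0.85)
  # predictive means track the observations on the log scale
  expect_gt(stats::cor(log1p(s$pred_mean[ok]), log1p(s$incidence[ok])), 0.95)
})

test_that("posterior summaries round-trip through CSV", {
  post <- seasonal_fixture()$posterior
  path <- withr::local_tempfile(fileext = ".csv")
  write_rt_summary(post, path)
  tab <- utils::read.csv(path)
  expect_identical(names(tab), names(post$summary))
  expect_equal(tab$mean_rt, post$summary$mean_rt, tolerance = 1e-6)
})
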