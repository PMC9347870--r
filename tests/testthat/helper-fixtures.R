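# Shared fixtures. The seasonal fixture is computed once per test run and
# memoised; it uses a 600-point grid so the whole suite stays fast while the
# grid-sensitivity tests check that resolution does not matter.

default_gt <- function() discretize_gamma(3, 0.375)

test_grid <- function(n = 600, min_r = 0.05, max_r = 6) {
  rt_grid(min_r, max_r, n)
}

.fixture_cache <- new.env(parent = emptyenv())

seasonal_fixture <- function() {
  if (is.null(.fixture_cache$seasonal)) {
    gt <- default_gt()
    profile <- seasonal_rt_profile(300)
    traj <- simulate_renewal(profile, gt, seed_cases = 50, rng_seed = 1)
    post <- estimate_rt(traj$incidence, gt, grid = test_grid(),
                        compute_prediction = FALSE)
    .fixture_cache$seasonal <- list(gt = gt, profile = profile, traj = traj,
                                    posterior = post)
  }
  .fixture_cache$seasonal
}
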