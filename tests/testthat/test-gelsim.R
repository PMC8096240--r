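test_that("induction_probability obeys the dose-response law", {
  expect_equal(induction_probability(0.3, 0.1, 0), 0)
  expect_equal(induction_probability(0, 0, 100), 0)
  # k_r = 0 reduces to 1 - exp(-k_f * D)
  expect_equal(induction_probability(0.01, 0, 50), 1 - exp(-0.5))
  # linear at low dose: relative error < 1% when k_f * D <= 0.02
  p <- induction_probability(1e-4, 0, 200)
  expect_lt(abs(p - 1e-4 * 200) / (1e-4 * 200), 0.01)
  # k_f = k_r at large dose tends to the steady state 0.5
  expect_equal(induction_probability(0.1, 0.1, 1e6), 0.5)
  # monotone in dose, bounded by k_f / (k_f + k_r)
  doses <- seq(0, 500, by = 10)
  pv <- induction_probability(0.004, 0.001, doses)
  expect_true(all(diff(pv) > 0))
  expect_true(all(pv < 0.004 / 0.005))
  expect_error(induction_probability(-1, 0, 1), ">= 0")
  expect_error(induction_probability(1, 0, -1), ">= 0")
})

test_that("expected_lane reproduces the worked single-hit examples", {
  l1 <- expected_lane(0.1, n_molecules = 1000)
  expect_equal(l1$volumes, 100)
  expect_equal(l1$full_length_volume, 900)

  l2 <- expected_lane(c(0.1, 0.2), n_molecules = 1000)
  expect_equal(l2$volumes, c(100, 180))
  expect_equal(l2$full_length_volume, 720)
})

test_that("expected_lane equals the 2^k brute-force oracle exactly", {
  set.seed(21)
  for (k in c(1, 5, 12)) {
    p <- runif(k, 0, 0.2)
    b <- runif(k, 0, 0.01)
    lane <- expected_lane(p, background = b, n_molecules = 1e6)
    q <- 1 - (1 - b) * (1 - p)
    oracle <- brute_force_lane(q, 1e6)
    expect_equal(lane$volumes, oracle$volumes, tolerance = 1e-12)
    expect_equal(lane$full_length_volume, oracle$full_length_volume,
                 tolerance = 1e-12)
    # volume conservation
    expect_equal(sum(lane$volumes) + lane$full_length_volume, 1e6)
  }
})

test_that("simulate_lane is seed-deterministic and converges to expectation", {
  p <- c(0.05, 0.1, 0.02)
  nm <- noise_model(molecules_per_lane = 1e6, volume_cv = 0.1, background = 0)
  a <- simulate_lane(p, noise = nm, seed = 42)
  b <- simulate_lane(p, noise = nm, seed = 42)
  expect_identical(a$volumes, b$volumes)
  expect_identical(a$full_length_volume, b$full_length_volume)
  c2 <- simulate_lane(p, noise = nm, seed = 43)
  expect_false(identical(a$volumes, c2$volumes))

  # with cv = 0 each count is multinomial: check 3-sigma agreement
  nm0 <- noise_model(molecules_per_lane = 1e6, volume_cv = 0, background = 0)
  lane <- simulate_lane(p, noise = nm0, seed = 7)
  exp_lane <- expected_lane(p, n_molecules = 1e6)
  mu <- c(exp_lane$volumes, exp_lane$full_length_volume)
  obs <- c(lane$volumes, lane$full_length_volume)
  sd3 <- 3 * sqrt(mu * (1 - mu / 1e6))
  expect_true(all(abs(obs - mu) <= sd3))
  expect_equal(sum(obs), 1e6)
})

test_that("fraction_uncut implements the 60% single-hit guard boundary", {
  mk <- function(frac) lane_profile(1L, 100 * (1 - frac), 100 * frac)
  expect_false(fraction_uncut(mk(0.59))$single_hit)
  expect_true(fraction_uncut(mk(0.60))$single_hit)
  expect_true(fraction_uncut(mk(0.61))$single_hit)
  fu <- fraction_uncut(mk(0.72))
  expect_equal(fu$fraction, 0.72)
  expect_true(fu$single_hit)
})

test_that("sensitizer profiles plant the documented mode biases", {
  sites <- test_design()$sites

  uv <- sensitizer_profile(sites, "UV", seed = 3)
  expect_true(all(uv$k_f > 0))
  expect_equal(max(uv$k_f) / min(uv$k_f), 12, tolerance = 1e-9)
  # 5'-G suppression holds on average
  g5 <- substr(uv$context, 1, 1) == "G"
  expect_lt(mean(uv$k_f[g5]), mean(uv$k_f[!g5]))

  ac <- sensitizer_profile(sites, "acetone", seed = 3)
  tt <- substr(ac$context, 2, 3) == "TT"
  cc <- substr(ac$context, 2, 3) == "CC"
  expect_equal(sum(ac$k_f[tt]) / sum(ac$k_f), 0.79, tolerance = 1e-9)
  expect_true(all(ac$k_f[cc] == 0))

  nfx <- sensitizer_profile(sites, "NFX", seed = 3)
  expect_true(all(nfx$k_f[!tt] == 0))
  expect_true(all(nfx$k_f[tt] > 0))
})

test_that("calibrate_kinetics hits the target uncut fraction", {
  sites <- test_design()$sites
  kin <- sensitizer_profile(sites, "UV", seed = 3)
  dose <- 24000
  cal <- calibrate_kinetics(kin, dose, target_uncut = 0.65)
  p <- induction_probability(cal$k_f, cal$k_r, dose)
  expect_equal(prod(1 - p), 0.65, tolerance = 1e-8)
  lane <- expected_lane(p, n_molecules = 1e6, positions = cal$position)
  expect_true(fraction_uncut(lane)$single_hit)
})

test_that("pre-steady-state regime is linear within 3%", {
  set.seed(31)
  k_f <- runif(20, 0.5, 2)
  dose <- 0.04 / sum(k_f)  # sum(q) ~= 0.04 <= 0.05
  p <- induction_probability(k_f, 0, dose)
  expect_lte(sum(p), 0.05)
  lane <- expected_lane(p, n_molecules = 1)
  f <- relative_frequency(lane)$f
  rel_err <- abs(f - k_f * dose) / (k_f * dose)
  expect_true(all(rel_err < 0.03))
})

test_that("simulate_experiment produces 2 x loadings x replicates lanes", {
  d <- test_design()
  kin <- calibrate_kinetics(sensitizer_profile(d$sites, "UV", seed = 3),
                            dose = 24000, target_uncut = 0.65)
  cond <- irradiation_condition("NB UVB", 40, 600, kin)
  loadings <- list(c(1, 52), c(42, 110), c(86, 129))
  lanes <- simulate_experiment(d, cond, loadings, replicates = 3,
                               noise = noise_model(1e6, 0.1, 5e-4), seed = 1)
  expect_length(lanes, 18L)
  roles <- vapply(lanes, `[[`, character(1), "role")
  expect_equal(sum(roles == "control"), 9L)
  expect_equal(sum(roles == "treated"), 9L)
  expect_setequal(vapply(lanes, `[[`, integer(1), "replicate_id"), 1:3)
  expect_setequal(vapply(lanes, `[[`, integer(1), "loading_id"), 1:3)
  # deterministic given seed
  lanes2 <- simulate_experiment(d, cond, loadings, replicates = 3,
                                noise = noise_model(1e6, 0.1, 5e-4), seed = 1)
  expect_identical(lanes[[5]]$volumes, lanes2[[5]]$volumes)
})

test_that("simulate_experiment rejects bad loading windows", {
  d <- test_design()
  kin <- sensitizer_profile(d$sites, "UV", seed = 3)
  cond <- irradiation_condition("x", 40, 600, kin)
  # gap: sites between 60 and 86 uncovered
  expect_error(simulate_experiment(d, cond, list(c(1, 60), c(86, 129))),
               "uncovered")
  # insufficient shared sites between consecutive windows
  expect_error(simulate_experiment(d, cond, list(c(1, 80), c(80, 129))),
               "share")
})

test_that("lane_profile validates its inputs", {
  expect_error(lane_profile(c(1, 2), c(1, 2, 3), 1), "equal length")
  expect_error(lane_profile(c(2, 1), c(1, 2), 1), "increasing")
  expect_error(lane_profile(c(1, 2), c(-1, 2), 1), "non-negative")
})
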