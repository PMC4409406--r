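test_that("CRW generator is deterministic and respects its bout structure", {
  p <- crw_open(500, turn_kappa = 2)
  a <- generate_crw(p, seed = 42)
  b <- generate_crw(p, seed = 42)
  expect_identical(a, b)
  expect_false(identical(a, generate_crw(p, seed = 43)))

  # absorbing move state: no rest intervals
  p0 <- crw_open(300, p_move_to_rest = 0, p_rest_to_move = 0.5,
                 start_state = "move")
  tr <- generate_crw(p0, seed = 1)
  expect_identical(sum(tr$state == "rest", na.rm = TRUE), 0L)

  # near-degenerate von Mises: path is collinear within numerical tolerance
  pk <- crw_open(100, p_move_to_rest = 0, turn_kappa = 1e6)
  trk <- generate_crw(pk, seed = 2)
  ang <- turning_angles(trk, rest_threshold_cm = 0)
  expect_lt(max(abs(ang$theta_deg)), 0.5)
})

test_that("CRW parameter validation names the offending field", {
  expect_error(crw_params(p_move_to_rest = 1.5), "p_move_to_rest")
  expect_error(crw_params(n_steps = 0), "n_steps")
  expect_error(crw_params(turn_kappa = -1), "turn_kappa")
  expect_error(crw_params(jitter_sd_cm = -0.1), "jitter_sd_cm")
  expect_error(step_powerlaw(mu = 1), "mu")
  expect_error(step_powerlaw(x_min = 0), "x_min")
})

test_that("rest-state occupancy converges to the two-state stationary value", {
  p_mr <- 0.1; p_rm <- 0.15
  p <- crw_open(1e5, p_move_to_rest = p_mr, p_rest_to_move = p_rm)
  tr <- generate_crw(p, seed = 9)
  occ <- mean(tr$state[-1] == "rest")
  target <- p_mr / (p_mr + p_rm)
  # binomial SE inflated by the chain's autocorrelation (1+rho)/(1-rho)
  rho <- 1 - p_mr - p_rm
  se <- sqrt(target * (1 - target) / 1e5 * (1 + rho) / (1 - rho))
  expect_lt(abs(occ - target), 3 * se)
})

test_that("moving step lengths follow the requested exponential model", {
  p <- crw_open(10000, p_move_to_rest = 0.2, p_rest_to_move = 0.3,
                step_model = step_exponential(2))
  tr <- generate_crw(p, seed = 5)
  st <- step_lengths(tr, rest_threshold_cm = 0)
  mv <- st$step_cm[tr$state[-1] == "move"]
  expect_lt(abs(mean(mv) - 0.5), 3 * 0.5 / sqrt(length(mv)))
})

test_that("von Mises sampler concentration is recovered by circular_summary", {
  set.seed(77)
  th <- rvonmises(1e4, 0, 5) * 180 / pi
  k <- circular_summary(th)$kappa
  expect_lt(abs(k - 5) / 5, 0.10)
  # uniform limit
  u <- rvonmises(2000, 0, 0)
  expect_true(all(u > -pi & u <= pi))
})

test_that("Brownian generator matches the 2-D diffusion law and is reproducible", {
  expect_error(generate_brownian(1, 0.1, 1), "n_steps")
  b0 <- generate_brownian(10, 0, seed = 1)
  expect_true(all(b0$x_cm == 0) && all(b0$y_cm == 0))
  expect_identical(generate_brownian(100, 0.1, 3), generate_brownian(100, 0.1, 3))

  b <- generate_brownian(1e5, 0.1, seed = 4)
  for (k in c(10L, 100L)) {
    disp2 <- (b$x_cm[-seq_len(k)] - head(b$x_cm, -k))^2 +
      (b$y_cm[-seq_len(k)] - head(b$y_cm, -k))^2
    msd <- mean(disp2)
    expect_lt(abs(msd - k * 2 * 0.1^2) / (k * 2 * 0.1^2), 0.15)
  }
})

test_that("reference paths have their analytic geometry", {
  st <- generate_reference_path("straight", 100, 101)
  expect_identical(nrow(st), 101L)
  expect_true(all(abs(turning_angles(st, 0)$theta_deg) < 1e-9))

  k1 <- generate_reference_path("koch", 90, level = 1)
  expect_identical(nrow(k1), 5L)
  seglen <- sqrt(diff(k1$x_cm)^2 + diff(k1$y_cm)^2)
  expect_equal(seglen, rep(30, 4), tolerance = 1e-12)

  k5 <- generate_reference_path("koch", 100, level = 5)
  len <- sum(sqrt(diff(k5$x_cm)^2 + diff(k5$y_cm)^2))
  expect_equal(len, (4 / 3)^5 * 100, tolerance = 1e-9)

  expect_error(generate_reference_path("koch", 100, level = 7), "level")
})

test_that("density-experiment cohorts are labelled, seeded and validated", {
  lo <- crw_open(200, p_move_to_rest = 0.15, p_rest_to_move = 0.35)
  hi <- crw_open(200, p_move_to_rest = 0.30, p_rest_to_move = 0.20)
  coh <- generate_density_experiment(list(low = lo, high = hi),
                                     n_individuals = 5, seed = 11)
  expect_setequal(unique(coh$treatment), c("low", "high"))
  expect_identical(dplyr::n_distinct(coh$individual_id), 10L)
  expect_identical(coh,
                   generate_density_experiment(list(low = lo, high = hi),
                                               n_individuals = 5, seed = 11))
  expect_error(generate_density_experiment(list(low = lo, high = hi),
                                           n_individuals = 1, seed = 1),
               "n_individuals")
  expect_error(generate_density_experiment(list(only = lo),
                                           n_individuals = 5, seed = 1),
               "2")
  expect_message(generate_density_experiment(list(a = lo, b = lo),
                                             n_individuals = 3, seed = 1),
                 "null scenario")
})

test_that("a generated rest-occupancy contrast is recovered in group means", {
  lo <- crw_open(400, p_move_to_rest = 0.15, p_rest_to_move = 0.35,
                 step_model = step_powerlaw(3, 0.3), jitter_sd_cm = 0.02)
  hi <- crw_open(400, p_move_to_rest = 0.30, p_rest_to_move = 0.20,
                 step_model = step_powerlaw(3, 0.3), jitter_sd_cm = 0.02)
  coh <- generate_density_experiment(list(lo = lo, hi = hi),
                                     n_individuals = 8, seed = 21)
  im <- quick_individual_metrics(coh)
  means <- tapply(im$resting_fraction, im$treatment, mean)
  expect_lt(abs(means[["lo"]] - 0.3), 0.08)
  expect_lt(abs(means[["hi"]] - 0.6), 0.08)
  expect_gt(means[["hi"]], means[["lo"]])
})
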