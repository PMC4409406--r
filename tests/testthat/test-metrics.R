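seg_from_xy <- function(x, y) tibble::tibble(time_s = seq_along(x) - 1,
                                             x_cm = x, y_cm = y)

test_that("step lengths are Euclidean per-interval distances with rest flags", {
  s <- seg_from_xy(c(0, 3), c(0, 4))
  st <- step_lengths(s)
  expect_equal(st$step_cm, 5)
  expect_true(st$is_relocation)

  s2 <- seg_from_xy(c(1, 1), c(2, 2))
  st2 <- step_lengths(s2)
  expect_identical(st2$step_cm, 0)
  expect_false(st2$is_relocation)

  expect_error(step_lengths(seg_from_xy(0, 0)), "2 points")

  # brute-force oracle on a random 50-point segment
  set.seed(12)
  s3 <- seg_from_xy(cumsum(rnorm(50)), cumsum(rnorm(50)))
  st3 <- step_lengths(s3)
  oracle <- vapply(1:49, function(i) {
    sqrt((s3$x_cm[i + 1] - s3$x_cm[i])^2 + (s3$y_cm[i + 1] - s3$y_cm[i])^2)
  }, numeric(1))
  expect_equal(st3$step_cm, oracle)

  # a step exactly at the threshold counts as relocation
  tie <- step_lengths(seg_from_xy(c(0, 0.1), c(0, 0)))
  expect_true(tie$is_relocation)
})

test_that("resting fraction partitions intervals exactly", {
  all_rest <- step_lengths(seg_from_xy(cumsum(rep(0.05, 11)), rep(0, 11)))
  expect_identical(resting_fraction(all_rest)$resting_fraction, 1)

  alt <- step_lengths(seg_from_xy(c(0, cumsum(rep(c(0.05, 1), 5))),
                                  rep(0, 11)))
  rf <- resting_fraction(alt)
  expect_identical(rf$resting_fraction, 0.5)
  expect_identical(rf$resting_fraction + mean(alt$is_relocation), 1)
  expect_error(resting_fraction(alt[0, ]), "at least one")
})

test_that("resting fraction recovers the generating bout occupancy", {
  # moving steps bounded away from the 0.1 cm threshold so the step-based
  # resting fraction estimates bout occupancy rather than mixing in short
  # moving steps
  p <- crw_open(1e4, p_move_to_rest = 0.2, p_rest_to_move = 0.3,
                step_model = step_powerlaw(3, 0.3),
                jitter_sd_cm = 0.02)
  tr <- generate_crw(p, seed = 13)
  rf <- resting_fraction(step_lengths(tr))$resting_fraction
  rho <- 1 - 0.5
  se <- sqrt(0.4 * 0.6 / 1e4 * (1 + rho) / (1 - rho))
  expect_lt(abs(rf - 0.4), 3 * se + 0.01)  # small allowance for jitter misclassification
})

test_that("turning angles follow the signed ccw convention and break at rests", {
  left <- turning_angles(seg_from_xy(c(0, 1, 1), c(0, 0, 1)))
  expect_equal(left$theta_deg, 90)
  right <- turning_angles(seg_from_xy(c(0, 1, 1), c(0, 0, -1)))
  expect_equal(right$theta_deg, -90)
  rev_ <- turning_angles(seg_from_xy(c(0, 1, 0), c(0, 0, 0)))
  expect_equal(rev_$theta_deg, 180)  # reversal maps to the closed endpoint
  straight <- turning_angles(seg_from_xy(0:5, rep(0, 6)))
  expect_true(all(abs(straight$theta_deg) < 1e-9))
  expect_error(turning_angles(seg_from_xy(0:1, c(0, 0))), "3 points")

  # resting interval between two relocations: no angle across the rest
  s <- seg_from_xy(c(0, 1, 1.0001, 2), c(0, 0, 0, 1))
  expect_identical(nrow(turning_angles(s)), 0L)

  # all angles in (-180, 180]
  set.seed(5)
  s2 <- seg_from_xy(cumsum(rnorm(200)), cumsum(rnorm(200)))
  a <- turning_angles(s2)$theta_deg
  expect_true(all(a > -180 & a <= 180))
})

test_that("turning angles and steps are invariant under rigid motions", {
  set.seed(8)
  s <- seg_from_xy(cumsum(rnorm(40)), cumsum(rnorm(40)))
  # threshold 0 isolates the geometric invariance from rest classification,
  # which is legitimately sensitive to steps sitting exactly at the cutoff
  a0 <- turning_angles(s, 0)$theta_deg
  st0 <- step_lengths(s, 0)$step_cm
  for (ang in c(30, 117.3, -64)) {
    r <- rotate_segment(s, ang)
    r$x_cm <- r$x_cm + 12.3; r$y_cm <- r$y_cm - 4.56
    expect_equal(turning_angles(r, 0)$theta_deg, a0, tolerance = 1e-9)
    expect_equal(step_lengths(r, 0)$step_cm, st0, tolerance = 1e-9)
  }
  # uniform scaling scales steps, keeps angles
  sc <- s; sc$x_cm <- 3 * s$x_cm; sc$y_cm <- 3 * s$y_cm
  expect_equal(step_lengths(sc, 0)$step_cm, 3 * st0, tolerance = 1e-12)
  expect_equal(turning_angles(sc, 0)$theta_deg, a0, tolerance = 1e-9)
})

test_that("stop rate counts move-to-rest transitions per metre", {
  no_rest <- step_lengths(seg_from_xy(cumsum(rep(1, 11)), rep(0, 11)))
  expect_identical(stops_per_distance(no_rest), 0)

  # 50 cm travelled then one stop: 2 stops per metre
  s <- seg_from_xy(c(0, 25, 50, 50.0001), c(0, 0, 0, 0))
  expect_equal(stops_per_distance(step_lengths(s)), 1 / (50.0001 / 100),
               tolerance = 1e-6)

  # oracle on a simulated bout process
  p <- crw_open(2000, p_move_to_rest = 0.2, p_rest_to_move = 0.3)
  st <- step_lengths(generate_crw(p, seed = 6))
  r <- st$is_relocation
  oracle <- sum(head(r, -1) & !tail(r, -1)) / (sum(st$step_cm) / 100)
  expect_equal(stops_per_distance(st), oracle)

  all_rest <- step_lengths(seg_from_xy(rep(0, 5), rep(0, 5)))
  expect_error(stops_per_distance(all_rest), "relocation distance")
})

test_that("step-distribution classification identifies the generating model", {
  set.seed(19)
  fe <- fit_step_distribution(0.1 + rexp(1e4, 1), x_min = 0.1)
  expect_identical(fe$verdict, "exponential")
  fp <- fit_step_distribution(0.1 * (1 - runif(1e4))^(-1), x_min = 0.1)
  expect_identical(fp$verdict, "powerlaw")
  f30 <- fit_step_distribution(0.1 + rexp(30, 1), x_min = 0.1)
  expect_identical(f30$verdict, "inconclusive")

  expect_error(fit_step_distribution(c(0.01, 0.02), x_min = 0.1), "x_min")

  td <- tidy(fe)
  expect_identical(td$model, c("exponential", "powerlaw"))
  expect_true(all(is.finite(td$aic)))
  gl <- glance(fp)
  expect_identical(gl$verdict, "powerlaw")
  expect_s3_class(autoplot(fe), "ggplot")
})
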