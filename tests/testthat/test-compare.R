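per_ind_table <- function(vals_by_group, col = "resting_fraction") {
  dplyr::bind_rows(purrr::imap(vals_by_group, function(v, g) {
    d <- tibble::tibble(individual_id = sprintf("%s_%d", g, seq_along(v)),
                        treatment = g)
    d[[col]] <- v
    d
  }))
}

test_that("the dispatch table maps every metric and group count to one test", {
  set.seed(51)
  two <- per_ind_table(list(a = rnorm(10, 0.4, 0.05),
                            b = rnorm(10, 0.4, 0.05)))
  three <- per_ind_table(list(a = rnorm(8, 0.4, 0.05),
                              b = rnorm(8, 0.4, 0.05),
                              c = rnorm(8, 0.4, 0.05)))
  expect_identical(compare_treatments(two, "resting_time")$test,
                   "Welch t-test")
  expect_identical(compare_treatments(three, "resting_time")$test,
                   "one-way ANOVA")

  st2 <- per_ind_table(list(a = rexp(10), b = rexp(10)), "mean_step_cm")
  st3 <- per_ind_table(list(a = rexp(8), b = rexp(8), c = rexp(8)),
                       "mean_step_cm")
  expect_identical(compare_treatments(st2, "step_length")$test,
                   "Wilcoxon rank-sum")
  expect_identical(compare_treatments(st3, "step_length")$test,
                   "Kruskal-Wallis")

  fd3 <- per_ind_table(list(a = runif(8, 1.05, 1.3), b = runif(8, 1.05, 1.3),
                            c = runif(8, 1.05, 1.3)), "D")
  res <- compare_treatments(fd3, "fractal_dimension")
  expect_identical(res$test, "one-way ANOVA")
  expect_identical(res$transform, "log(D-1)")

  ang <- tibble::tibble(theta_deg = runif(60, -180, 180),
                        treatment = rep(c("a", "b"), each = 30))
  expect_identical(compare_treatments(ang, "turning_angle")$test,
                   "Watson-Wheeler")
})

test_that("degenerate and extreme group contrasts give the expected p-values", {
  v <- c(0.31, 0.35, 0.4, 0.43, 0.5)
  ident <- per_ind_table(list(a = v, b = v))
  res <- compare_treatments(ident, "resting_time")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  set.seed(52)
  strong <- per_ind_table(list(a = rnorm(20, 0.3, 0.05),
                               b = rnorm(20, 0.6, 0.05)))
  expect_lt(compare_treatments(strong, "resting_time")$p_value, 0.001)
})

test_that("fractal values at or below 1 are clipped with a warning before log(D-1)", {
  d <- per_ind_table(list(a = c(1.0, 1.1, 1.2, 1.3),
                          b = c(1.05, 1.15, 1.22, 1.31)), "D")
  expect_warning(res <- compare_treatments(d, "fractal_dimension"),
                 "clipped")
  expect_identical(res$transform, "log(D-1)")
  expect_true(res$p_value >= 0 && res$p_value <= 1)
})

test_that("comparison preconditions are enforced", {
  small <- per_ind_table(list(a = c(0.1, 0.2), b = c(0.3, 0.4)))
  expect_error(compare_treatments(small, "resting_time"), "3 individuals")
  one <- per_ind_table(list(a = c(0.1, 0.2, 0.3)))
  expect_error(compare_treatments(one, "resting_time"), "2 groups")
  expect_error(compare_treatments(small, "resting_time", value = "nope"),
               "nope")
})

test_that("summary table cells match a spreadsheet-style manual computation", {
  # three individuals, one segment each, built by hand
  seg <- function(ind, tr, x, y, t0 = 0) tibble::tibble(
    segment_id = paste0(ind, "_s1"), individual_id = ind, treatment = tr,
    time_s = t0 + seq_along(x) - 1, x_cm = x, y_cm = y)
  s1 <- seg("i1", "ctrl", c(20, 21, 22, 23, 24, 24.00005), rep(20, 6))
  s2 <- seg("i2", "ctrl", c(30, 32, 34, 36, 38), rep(30, 5))
  s3 <- seg("i3", "trt", c(40, 41, 41.00005, 42, 43.5), rep(40, 5))
  segs <- dplyr::bind_rows(s1, s2, s3)

  st <- build_summary_table(segs, divider = FALSE,
                            recording_points_per_individual = 100)
  ctrl <- st[st$treatment == "ctrl", ]
  expect_identical(ctrl$n_paths, 2L)
  expect_equal(ctrl$available_points_pct, 100 * 11 / 200)
  expect_equal(ctrl$duration_mean_s, mean(c(5, 4)))
  # i1: 5 steps, one resting -> 0.2; i2: 4 steps, none resting -> 0
  expect_equal(ctrl$resting_pct_mean, 100 * mean(c(1 / 5, 0)))
  # mean relocation step: i1 = 1, i2 = 2
  expect_equal(ctrl$step_cm_mean, mean(c(1, 2)))
  trt <- st[st$treatment == "trt", ]
  expect_identical(trt$n_individuals, 1L)
  expect_true(is.na(trt$step_cm_sd))  # single individual: SD missing
  expect_equal(trt$resting_pct_mean, 100 * 1 / 4)
})

test_that("individual metrics pool intervals and average segment dimensions", {
  p <- crw_open(300, turn_kappa = 2, jitter_sd_cm = 0.02)
  coh <- suppressMessages(generate_density_experiment(
    list(a = p, b = p), n_individuals = 3, seed = 61))
  coh$segment_id <- paste0(coh$individual_id, "_s1")
  sm <- segment_metrics(coh, divider = divider_config(0.3, 15, 40))
  expect_identical(nrow(sm), 6L)
  im <- individual_metrics(sm)
  expect_identical(nrow(im), 6L)
  expect_true(all(c("resting_fraction", "mean_step_cm", "D") %in% names(im)))
  # single-segment individuals: pooled metrics equal the segment's
  expect_equal(im$resting_fraction[order(im$individual_id)],
               sm$resting_fraction[order(sm$individual_id)])

  # multi-segment individual: pooling is interval-weighted, D is unweighted
  two <- sm[1:2, ]
  two$individual_id <- "same"
  two$treatment <- "a"
  im2 <- individual_metrics(two)
  expect_identical(nrow(im2), 1L)
  expect_equal(im2$resting_fraction,
               sum(two$resting_fraction * two$n_steps) / sum(two$n_steps))
  expect_equal(im2$mean_step_cm,
               sum(two$mean_step_cm * two$n_relocations) /
                 sum(two$n_relocations))
  expect_equal(im2$D, mean(two$D))
  expect_true(im2$resting_fraction <= max(two$resting_fraction) &&
                im2$resting_fraction >= min(two$resting_fraction))
})
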