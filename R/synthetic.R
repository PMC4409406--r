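#' Step-length models for the correlated random walk
#'
#' `step_exponential()` draws moving step lengths from an exponential
#' distribution (light tail, characteristic scale `1/rate`).
#' `step_powerlaw()` draws from a Pareto distribution with density
#' proportional to `x^-mu` above a hard lower cutoff `x_min`, the simplest
#' heavy-tailed ("Levy-like") contrast to the exponential.
#'
#' @param rate Exponential rate per cm (mean moving step is `1/rate` cm).
#' @param mu Power-law exponent, must exceed 1.
#' @param x_min Lower cutoff in cm, must be positive.
#' @return A step-model object used by [crw_params()].
#' @export
step_exponential <- function(rate = 2) {
  assert_number(rate, "rate", lower = 1e-12)
  structure(list(kind = "exponential", rate = rate), class = "step_model")
}

#' @rdname step_exponential
#' @export
step_powerlaw <- function(mu = 2, x_min = 0.1) {
  if (!is.numeric(mu) || length(mu) != 1L || is.na(mu) || mu <= 1) {
    abort("`mu` must be a single number > 1")
  }
  if (!is.numeric(x_min) || length(x_min) != 1L || is.na(x_min) || x_min <= 0) {
    abort("`x_min` must be a single positive number")
  }
  structure(list(kind = "powerlaw", mu = mu, x_min = x_min),
            class = "step_model")
}

draw_steps <- function(model, n) {
  if (n == 0L) return(numeric(0))
  switch(model$kind,
    exponential = rexp(n, rate = model$rate),
    powerlaw = model$x_min * (1 - runif(n))^(-1 / (model$mu - 1)),
    abort("unknown step model")
  )
}

#' Parameters of the two-state correlated random walk
#'
#' Bundles and validates the generative parameters of the synthetic walker:
#' a move/rest two-state Markov chain at 1-s resolution, moving steps drawn
#' from a step-length model, turning angles drawn from a von Mises
#' distribution centred on straight-ahead, Gaussian positional jitter on the
#' observed coordinates, and specular reflection at the arena walls.
#' Heading persists unchanged through rest bouts.
#'
#' @param n_steps Number of 1-s intervals (the trajectory has
#'   `n_steps + 1` points).
#' @param p_move_to_rest,p_rest_to_move Per-second transition probabilities
#'   in `[0, 1]`. The stationary rest-state occupancy of the chain is
#'   `p_move_to_rest / (p_move_to_rest + p_rest_to_move)`.
#' @param step_model A [step_exponential()] or [step_powerlaw()] object.
#' @param turn_kappa von Mises concentration (>= 0) of per-step turning
#'   angles; 0 gives uniform turning, large values near-straight motion.
#' @param jitter_sd_cm Standard deviation (cm) of the positional observation
#'   noise added independently to each recorded coordinate.
#' @param start_xy_cm Initial position, cm from the bottom-left arena corner.
#' @param start_state Initial bout state, `"move"` or `"rest"`.
#' @param arena [arena_config()] providing the reflecting boundary.
#' @return A validated `crw_params` object.
#' @export
crw_params <- function(n_steps = 3600,
                       p_move_to_rest = 0.1,
                       p_rest_to_move = 0.2,
                       step_model = step_exponential(2),
                       turn_kappa = 2,
                       jitter_sd_cm = 0.02,
                       start_xy_cm = c(50, 50),
                       start_state = c("move", "rest"),
                       arena = arena_config()) {
  n_steps <- assert_count(n_steps, "n_steps", lower = 1L)
  assert_number(p_move_to_rest, "p_move_to_rest", 0, 1)
  assert_number(p_rest_to_move, "p_rest_to_move", 0, 1)
  if (!inherits(step_model, "step_model")) {
    abort("`step_model` must be built with step_exponential() or step_powerlaw()")
  }
  assert_number(turn_kappa, "turn_kappa", lower = 0)
  assert_number(jitter_sd_cm, "jitter_sd_cm", lower = 0)
  if (!is.numeric(start_xy_cm) || length(start_xy_cm) != 2L ||
      anyNA(start_xy_cm)) {
    abort("`start_xy_cm` must be a numeric vector of length 2")
  }
  start_state <- match.arg(start_state)
  stopifnot(inherits(arena, "arena_config"))
  if (start_xy_cm[1] < 0 || start_xy_cm[1] > arena$width_cm ||
      start_xy_cm[2] < 0 || start_xy_cm[2] > arena$height_cm) {
    abort("`start_xy_cm` must lie inside the arena")
  }
  structure(
    list(n_steps = n_steps, p_move_to_rest = p_move_to_rest,
         p_rest_to_move = p_rest_to_move, step_model = step_model,
         turn_kappa = turn_kappa, jitter_sd_cm = jitter_sd_cm,
         start_xy_cm = start_xy_cm, start_state = start_state, arena = arena),
    class = "crw_params")
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler; at `kappa = 0` the circular uniform is
#' returned directly.
#'
#' @param n Number of draws.
#' @param mu Mean direction, radians.
#' @param kappa Concentration parameter, >= 0.
#' @return Angles in radians, wrapped to `(-pi, pi]`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  n <- assert_count(n, "n", lower = 0L)
  assert_number(kappa, "kappa", lower = 0)
  if (n == 0L) return(numeric(0))
  if (kappa < 1e-10) {
    theta <- runif(n, -pi, pi)
  } else {
    a <- 1 + sqrt(1 + 4 * kappa^2)
    b <- (a - sqrt(2 * a)) / (2 * kappa)
    r <- (1 + b^2) / (2 * b)
    theta <- numeric(n)
    got <- 0L
    while (got < n) {
      m <- max(16L, ceiling((n - got) * 1.4))
      u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
      z <- cos(pi * u1)
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
      acc <- f[ok]
      sgn <- sign(u3[ok] - 0.5)
      take <- min(length(acc), n - got)
      if (take > 0) {
        theta[(got + 1L):(got + take)] <-
          sgn[seq_len(take)] * acos(pmin(1, pmax(-1, acc[seq_len(take)])))
        got <- got + take
      }
    }
  }
  th <- theta + mu
  th - 2 * pi * floor((th + pi) / (2 * pi))
}

#' Simulate a correlated random walk with move/rest bouts
#'
#' Generates a 1-Hz trajectory of a single walker. Each 1-s interval is in a
#' move or rest bout according to a two-state Markov chain; moving intervals
#' advance the walker by a step drawn from the step-length model along a
#' heading updated by a von Mises turning angle, resting intervals leave the
#' true position unchanged (heading persists). Observed coordinates are the
#' true ones plus independent Gaussian jitter; the walker reflects specularly
#' at the arena walls.
#'
#' @param params A [crw_params()] object.
#' @param seed Integer seed; identical seed and parameters reproduce the
#'   trajectory exactly.
#' @return A tibble with one row per time point: `time_s`, observed `x_cm`,
#'   `y_cm`, noise-free `x_true_cm`, `y_true_cm`, and `state` — the bout
#'   state of the interval ending at that time point (`NA` for the first).
#' @export
generate_crw <- function(params, seed) {
  if (!inherits(params, "crw_params")) {
    abort("`params` must be built with crw_params()")
  }
  seed <- assert_count(seed, "seed", lower = 0L)
  set.seed(seed)
  n <- params$n_steps

  # bout state per interval: TRUE = move
  u <- runif(n)
  s <- logical(n)
  cur <- params$start_state == "move"
  for (i in seq_len(n)) {
    s[i] <- cur
    cur <- if (cur) u[i] >= params$p_move_to_rest else u[i] < params$p_rest_to_move
  }
  n_move <- sum(s)

  heading0 <- runif(1, -pi, pi)
  turns <- numeric(n)
  turns[s] <- rvonmises(n_move, 0, params$turn_kappa)
  lens <- numeric(n)
  lens[s] <- draw_steps(params$step_model, n_move)

  h <- heading0 + cumsum(turns)  # heading persists through rests (turn = 0)
  xt <- params$start_xy_cm[1] + c(0, cumsum(lens * cos(h)))
  yt <- params$start_xy_cm[2] + c(0, cumsum(lens * sin(h)))
  xt <- fold_reflect(xt, params$arena$width_cm)
  yt <- fold_reflect(yt, params$arena$height_cm)

  x <- xt + rnorm(n + 1, 0, params$jitter_sd_cm)
  y <- yt + rnorm(n + 1, 0, params$jitter_sd_cm)

  tibble(
    time_s = 0:n,
    x_cm = x, y_cm = y,
    x_true_cm = xt, y_true_cm = yt,
    state = c(NA_character_, ifelse(s, "move", "rest"))
  )
}

#' Simulate planar Brownian motion
#'
#' Isotropic Gaussian increments at unit (1 s) time spacing; the reference
#' plane-filling motion whose path has fractal dimension 2.
#'
#' @param n_steps Number of unit-time steps (>= 2).
#' @param step_sd_cm Per-axis standard deviation of each increment, cm.
#' @param seed Integer seed.
#' @param start_xy_cm Starting position (no boundary is applied).
#' @return A tibble with `time_s`, `x_cm`, `y_cm`.
#' @export
generate_brownian <- function(n_steps, step_sd_cm, seed, start_xy_cm = c(0, 0)) {
  n_steps <- assert_count(n_steps, "n_steps", lower = 2L)
  assert_number(step_sd_cm, "step_sd_cm", lower = 0)
  seed <- assert_count(seed, "seed", lower = 0L)
  set.seed(seed)
  x <- start_xy_cm[1] + c(0, cumsum(rnorm(n_steps, 0, step_sd_cm)))
  y <- start_xy_cm[2] + c(0, cumsum(rnorm(n_steps, 0, step_sd_cm)))
  tibble(time_s = 0:n_steps, x_cm = x, y_cm = y)
}

#' Reference paths with known fractal dimension
#'
#' A straight line (dimension exactly 1) or a triadic Koch polyline
#' (dimension `log 4 / log 3` within its self-similar scale range), used as
#' analytic oracles for the divider-method estimator.
#'
#' @param kind `"straight"` or `"koch"`.
#' @param extent_cm End-to-end extent of the path, cm.
#' @param n_points Number of points for the straight path.
#' @param level Koch construction depth, at most 6.
#' @return A tibble with `time_s`, `x_cm`, `y_cm`.
#' @export
generate_reference_path <- function(kind = c("straight", "koch"),
                                    extent_cm = 100,
                                    n_points = 101,
                                    level = 5) {
  kind <- match.arg(kind)
  assert_number(extent_cm, "extent_cm", lower = 1e-12)
  if (kind == "straight") {
    n_points <- assert_count(n_points, "n_points", lower = 2L)
    x <- seq(0, extent_cm, length.out = n_points)
    return(tibble(time_s = 0:(n_points - 1), x_cm = x, y_cm = 0))
  }
  level <- assert_count(level, "level", lower = 1L)
  if (level > 6L) abort("`level` must be at most 6")
  pts <- matrix(c(0, 0, 1, 0), ncol = 2, byrow = TRUE)
  rot60 <- matrix(c(cos(pi / 3), sin(pi / 3), -sin(pi / 3), cos(pi / 3)), 2, 2)
  for (l in seq_len(level)) {
    out <- vector("list", nrow(pts) - 1L)
    for (i in seq_len(nrow(pts) - 1L)) {
      p <- pts[i, ]; q <- pts[i + 1L, ]
      d <- (q - p) / 3
      a <- p + d
      b <- p + 2 * d
      peak <- a + as.numeric(rot60 %*% d)
      out[[i]] <- rbind(p, a, peak, b)
    }
    pts <- rbind(do.call(rbind, out), pts[nrow(pts), ])
  }
  pts <- unname(pts * extent_cm)
  tibble(time_s = 0:(nrow(pts) - 1L), x_cm = pts[, 1], y_cm = pts[, 2])
}

#' Simulate a multi-treatment density-style experiment
#'
#' Generates a labelled cohort of independent correlated-random-walk
#' trajectories, one walker per individual, with per-treatment generative
#' parameters — the synthetic analogue of observing 20 replicate individuals
#' under each experimental condition. Supplying identical parameters for all
#' treatments is the null scenario (flagged with a message, allowed).
#'
#' @param scenarios Named list of [crw_params()] objects, one per treatment
#'   (>= 2 treatments).
#' @param n_individuals Individuals per treatment (>= 3).
#' @param seed Integer master seed; per-individual sub-seeds are derived
#'   from it so the cohort is reproducible.
#' @return A tidy tibble of all trajectories with `individual_id` and
#'   `treatment` columns.
#' @export
generate_density_experiment <- function(scenarios, n_individuals, seed) {
  if (!is.list(scenarios) || length(scenarios) < 2L ||
      is.null(names(scenarios)) || any(names(scenarios) == "")) {
    abort("`scenarios` must be a named list of >= 2 crw_params objects")
  }
  if (!all(map_lgl(scenarios, inherits, "crw_params"))) {
    abort("every element of `scenarios` must be a crw_params object")
  }
  n_individuals <- assert_count(n_individuals, "n_individuals", lower = 3L)
  seed <- assert_count(seed, "seed", lower = 0L)
  if (length(unique(map(scenarios, unclass))) == 1L) {
    message("identical parameters across treatments: null scenario")
  }
  k <- length(scenarios)
  seeds <- matrix(derive_seeds(seed, k * n_individuals), nrow = k)
  res <- vector("list", k * n_individuals)
  idx <- 0L
  for (g in seq_len(k)) {
    for (i in seq_len(n_individuals)) {
      idx <- idx + 1L
      tr <- generate_crw(scenarios[[g]], seed = seeds[g, i])
      tr$individual_id <- sprintf("%s_%02d", names(scenarios)[g], i)
      tr$treatment <- names(scenarios)[g]
      res[[idx]] <- tr
    }
  }
  bind_rows(res)
}
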