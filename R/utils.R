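# internal validation + angle helpers

assert_number <- function(x, field, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", field,
                  format(lower), format(upper)))
  }
  invisible(x)
}

assert_count <- function(x, field, lower = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower ||
      x != as.integer(x)) {
    abort(sprintf("`%s` must be a whole number >= %d", field, lower))
  }
  invisible(as.integer(x))
}

# wrap degrees into (-180, 180]
wrap_deg <- function(x) {
  w <- x - 360 * floor((x + 180) / 360)
  w[w <= -180] <- w[w <= -180] + 360
  w
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# fold coordinates into [0, width]: equivalent to specular reflection at the
# walls for axis-aligned boxes
fold_reflect <- function(v, width) {
  m <- v %% (2 * width)
  ifelse(m > width, 2 * width - m, m)
}

# signed arc from `from` to `to` in (-180, 180]
arc_deg <- function(from, to) wrap_deg(to - from)

# draw sub-seeds from a master seed without leaking state
derive_seeds <- function(seed, n) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
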