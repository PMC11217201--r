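# Internal numerical helpers. Units convention: seconds and s^-1 internally,
# ml/min and min^-1 at user-facing boundaries.

#' Physical half-life of 15O in seconds
#'
#' Decay constant lambda = log(2) / half-life.
#' @export
O15_HALF_LIFE_S <- 122.24

min_to_s <- function(rate_per_min) rate_per_min / 60
s_to_min <- function(rate_per_s) rate_per_s * 60

#' @keywords internal
#' @noRd
stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
# seed = NULL leaves the global stream untouched (and advances it).
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stop_if(!is.numeric(seed) || length(seed) != 1L || is.na(seed),
          "seed must be a single integer")
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Exact integral of the piecewise-linear interpolant of (time, value)
# over [a, b]; endpoints interpolated into the grid.
pwl_integral <- function(time, value, a, b) {
  stop_if(a < time[1L] - 1e-9 || b > time[length(time)] + 1e-9,
          "integration range [", a, ", ", b, "] outside curve support")
  if (b <= a) return(0)
  inside <- time > a & time < b
  tt <- c(a, time[inside], b)
  vv <- c(stats::approx(time, value, xout = a, rule = 2)$y,
          value[inside],
          stats::approx(time, value, xout = b, rule = 2)$y)
  sum(diff(tt) * (vv[-1L] + vv[-length(vv)]) / 2)
}

# Frame averages of a piecewise-linear curve over a FrameSchedule.
frame_average <- function(time, value, schedule) {
  starts <- schedule$frame_starts
  ends <- starts + schedule$frame_durations
  vapply(seq_along(starts), function(k) {
    pwl_integral(time, value, starts[k], ends[k]) / schedule$frame_durations[k]
  }, numeric(1L))
}

# phi1 = (1 - exp(-k h)) / k and phi2 = (h - phi1) / k, the exponential
# integrator weights for a linear source term; stable as k -> 0.
exp_phi <- function(k, h) {
  if (k * h < 1e-8) {
    list(e = exp(-k * h), phi1 = h - k * h^2 / 2, phi2 = h^2 / 2 - k * h^3 / 6)
  } else {
    phi1 <- -expm1(-k * h) / k
    list(e = exp(-k * h), phi1 = phi1, phi2 = (h - phi1) / k)
  }
}

# y' = g(t) - k y with g piecewise linear on grid t (uniform or not),
# y(t[1]) = y0. Exact for the piecewise-linear g; returns y on the grid.
linear_decay_ode <- function(t, g, k, y0 = 0) {
  n <- length(t)
  y <- numeric(n)
  y[1L] <- y0
  for (j in seq_len(n - 1L)) {
    h <- t[j + 1L] - t[j]
    w <- exp_phi(k, h)
    slope <- (g[j + 1L] - g[j]) / h
    y[j + 1L] <- y[j] * w$e + g[j] * w$phi1 + slope * w$phi2
  }
  y
}
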