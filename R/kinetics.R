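# Phantom-specific one-tissue kinetic model: decay correction, forward
# model (analytic convolution for piecewise-linear input), and delay-aware
# bounded weighted least-squares fitting.

# Frame-averaged decay factor: mean of exp(-lambda (t - t0)) over each frame
# (duration-weighted, not the midpoint approximation).
frame_decay_factors <- function(schedule, half_life_s, reference_time = 0) {
  stop_if(half_life_s <= 0, "half-life must be positive")
  if (!is.finite(half_life_s)) return(rep(1, n_frames(schedule)))
  lambda <- log(2) / half_life_s
  t1 <- schedule$frame_starts - reference_time
  t2 <- frame_ends(schedule) - reference_time
  (exp(-lambda * t1) - exp(-lambda * t2)) / (lambda * schedule$frame_durations)
}

#' Apply or remove decay correction on a frame-sampled TAC
#'
#' Frame-wise multiplication by the exact frame-averaged decay factor
#' referenced to the TAC's `reference_time` (injection time by default).
#' `apply` turns a physical TAC into a decay-corrected one; `remove` is its
#' exact inverse. Correcting an already-corrected TAC (or un-correcting an
#' uncorrected one) is refused.
#'
#' @param tac A [sampled_tac()].
#' @param half_life_s Radionuclide half-life (s); default 15O.
#' @param direction `"apply"` or `"remove"`.
#' @return A [sampled_tac()] with the `decay_corrected` flag toggled.
#' @export
decay_correct <- function(tac, half_life_s = O15_HALF_LIFE_S,
                          direction = c("apply", "remove")) {
  stop_if(!inherits(tac, "sampled_tac"), "tac must be a sampled_tac")
  direction <- match.arg(direction)
  dfac <- frame_decay_factors(tac$schedule, half_life_s, tac$reference_time)
  if (direction == "apply") {
    stop_if(tac$decay_corrected, "TAC is already decay-corrected")
    sampled_tac(tac$schedule, tac$values / dfac, decay_corrected = TRUE,
                reference_time = tac$reference_time)
  } else {
    stop_if(!tac$decay_corrected, "TAC is not decay-corrected; nothing to remove")
    sampled_tac(tac$schedule, tac$values * dfac, decay_corrected = FALSE,
                reference_time = tac$reference_time)
  }
}

#' Convert a rate constant to a flow value
#'
#' The phantom's rate constants (min^-1) are converted to flows (ml/min) by
#' multiplication with the exchange-cylinder volume: `Q = q x Vcyl`.
#'
#' @param rate_min Rate constant (min^-1).
#' @param vcyl_ml Exchange-cylinder volume (ml), > 0.
#' @export
to_flow <- function(rate_min, vcyl_ml) {
  stop_if(vcyl_ml <= 0, "vcyl must be positive")
  rate_min * vcyl_ml
}

# Reconstruct a continuous input curve from frame-averaged values.
# "integral-spline" (default): interpolate the cumulative frame integral at
# the frame boundaries with a monotone (Hyman) cubic spline and
# differentiate — the reconstruction is smooth, nonnegative for
# nonnegative data and reproduces every frame average exactly.
# "conserved": piecewise-linear node values at frame boundaries solving the
# trapezoid-average equations sequentially (v0 = 0 anchor; negative
# overshoots clipped). "midpoint": frame values at frame midpoints.
input_curve_from_tac <- function(tac,
                                 method = c("integral-spline", "conserved",
                                            "midpoint"),
                                 time_step = 0.1) {
  method <- match.arg(method)
  sch <- tac$schedule
  if (method == "integral-spline") {
    edges <- c(sch$frame_starts[1L], frame_ends(sch))
    cum <- c(0, cumsum(pmax(tac$values, 0) * sch$frame_durations))
    f <- stats::splinefun(edges, cum, method = "hyman")
    tt <- seq(edges[1L], edges[length(edges)], by = time_step)
    continuous_curve(tt, pmax(f(tt, deriv = 1L), 0))
  } else if (method == "conserved") {
    v <- numeric(n_frames(sch) + 1L)
    for (k in seq_len(n_frames(sch)))
      v[k + 1L] <- max(0, 2 * tac$values[k] - v[k])
    continuous_curve(c(sch$frame_starts, frame_ends(sch)[n_frames(sch)]), v)
  } else {
    continuous_curve(c(sch$frame_starts[1L], frame_mids(sch)),
                     c(0, tac$values))
  }
}

# Convolution int_0^t g(s) exp(-k (t - s)) ds, exact for the
# piecewise-linear g on `grid`. On a uniform grid the per-segment analytic
# update is a constant-coefficient linear recurrence, evaluated in C via
# stats::filter; non-uniform grids take the explicit loop.
conv_exp <- function(grid, g, k) {
  n <- length(grid)
  h <- diff(grid)
  if (max(h) - min(h) < 1e-9 * max(h)) {
    w <- exp_phi(k, h[1L])
    slope <- (g[-1L] - g[-n]) / h[1L]
    cc <- g[-n] * w$phi1 + slope * w$phi2
    c(0, as.numeric(stats::filter(cc, w$e, method = "recursive")))
  } else {
    out <- numeric(n)
    for (j in seq_len(n - 1L)) {
      w <- exp_phi(k, h[j])
      slope <- (g[j + 1L] - g[j]) / h[j]
      out[j + 1L] <- out[j] * w$e + g[j] * w$phi1 + slope * w$phi2
    }
    out
  }
}

# Trapezoid frame-averaging weights as a (frames x grid) matrix, valid when
# every frame edge coincides with a grid point of the uniform grid; returns
# NULL otherwise (callers fall back to frame_average()).
frame_average_matrix <- function(grid, schedule) {
  h <- diff(grid)
  if (max(h) - min(h) > 1e-9 * max(h)) return(NULL)
  h <- h[1L]
  edges <- c(schedule$frame_starts, max(frame_ends(schedule)))
  idx <- round((edges - grid[1L]) / h) + 1L
  if (any(idx < 1L) || any(idx > length(grid)) ||
      max(abs(grid[idx] - edges)) > 1e-9) return(NULL)
  m <- matrix(0, n_frames(schedule), length(grid))
  for (k in seq_len(n_frames(schedule))) {
    i0 <- idx[k]; i1 <- idx[k + 1L]
    wts <- rep(h, i1 - i0 + 1L)
    wts[c(1L, length(wts))] <- h / 2
    m[k, i0:i1] <- wts / schedule$frame_durations[k]
  }
  m
}

#' Evaluate the phantom one-tissue forward model
#'
#' Measured cylinder-region model:
#' `M(t) = isf x Cin(t - delay) + qin x int_0^t Cin(s - delay) exp(-qout (t - s)) ds`
#' with rates in min^-1 converted internally to s^-1. The convolution is
#' computed analytically per segment of the piecewise-linear input. The
#' input is zero before its support. An optional variant scales the
#' convolution term by `(1 - isf)`.
#'
#' @param params Named list or vector with `qin_min`, `qout_min`, `isf`,
#'   `delay_s` (a [ground_truth()] works).
#' @param input A [continuous_curve()], or a [sampled_tac()] which is first
#'   reconstructed with `input_interp`.
#' @param times Evaluation times (s); returns a [continuous_curve()].
#' @param schedule Alternatively a [frame_schedule()]; the model is then
#'   frame-averaged and a [sampled_tac()] (decay-corrected) is returned.
#' @param isf_scaling `"none"` (default) leaves the convolution term
#'   unscaled; `"one-minus-isf"` multiplies it by `(1 - isf)`.
#' @param input_interp Reconstruction used when `input` is a sampled TAC;
#'   see details in the package vignette.
#' @param time_step Internal evaluation grid step (s).
#' @param half_life_s With a `schedule`, a finite half-life makes the
#'   frame prediction emulate the acquisition pipeline: the decay-free
#'   model is decayed, frame-averaged, and decay-corrected with the exact
#'   frame-averaged factor — i.e. a decay-weighted frame average. `Inf`
#'   (default) gives the plain frame average.
#' @export
forward_model <- function(params, input, times = NULL, schedule = NULL,
                          isf_scaling = c("none", "one-minus-isf"),
                          input_interp = "integral-spline", time_step = 0.1,
                          half_life_s = Inf) {
  isf_scaling <- match.arg(isf_scaling)
  p <- as.list(params)
  stop_if(is.null(p$qin_min) || is.null(p$qout_min) || is.null(p$isf) ||
            is.null(p$delay_s), "params needs qin_min, qout_min, isf, delay_s")
  stop_if(p$qin_min < 0 || p$qout_min < 0, "rate constants must be nonnegative")
  stop_if(p$delay_s < 0, "delay must be nonnegative")
  if (inherits(input, "sampled_tac"))
    input <- reconstruct_input(input, input_interp, half_life_s, time_step)
  stop_if(!inherits(input, "continuous_curve"), "input must be a curve or sampled TAC")
  stop_if(is.null(times) == is.null(schedule),
          "supply exactly one of times or schedule")

  t_end <- if (is.null(schedule)) max(times) else max(frame_ends(schedule))
  grid <- sort(unique(c(seq(0, t_end, by = time_step), t_end,
                        if (!is.null(times)) times)))
  g <- stats::approx(input$time + p$delay_s, input$values, xout = grid,
                     yleft = 0, rule = 2)$y
  conv <- conv_exp(grid, g, min_to_s(p$qout_min))
  scale <- if (isf_scaling == "one-minus-isf") 1 - p$isf else 1
  model <- p$isf * g + scale * min_to_s(p$qin_min) * conv
  if (is.null(schedule)) {
    continuous_curve(times, model[match(times, grid)])
  } else {
    if (is.finite(half_life_s)) {
      lambda <- log(2) / half_life_s
      decayed <- frame_average(grid, model * exp(-lambda * grid), schedule)
      vals <- decayed / frame_decay_factors(schedule, half_life_s)
    } else {
      vals <- frame_average(grid, model, schedule)
    }
    sampled_tac(schedule, vals, decay_corrected = TRUE)
  }
}

# Reconstruct the decay-corrected continuous input from a sampled input
# TAC. For a decay-corrected TAC and finite half-life the physical frame
# averages are recovered first (multiply back the frame decay factors),
# the physical curve is reconstructed (its frame averages are what the
# scanner actually measured), and the result is decay-corrected pointwise
# — this keeps the reconstruction consistent with the measurement process.
reconstruct_input <- function(tac, method = "integral-spline",
                              half_life_s = Inf, time_step = 0.1) {
  if (!is.finite(half_life_s) || !tac$decay_corrected ||
      method != "integral-spline")
    return(input_curve_from_tac(tac, method, time_step = time_step))
  dfac <- frame_decay_factors(tac$schedule, half_life_s, tac$reference_time)
  phys <- sampled_tac(tac$schedule, tac$values * dfac,
                      decay_corrected = FALSE, reference_time = tac$reference_time)
  curve <- input_curve_from_tac(phys, method, time_step = time_step)
  lambda <- log(2) / half_life_s
  continuous_curve(curve$time,
                   curve$values * exp(lambda * (curve$time - tac$reference_time)))
}

# Weighted least-squares solution for (qin, isf) given the two basis
# responses, with box constraints qin >= 0, 0 <= isf <= 1.
solve_linear_pair <- function(spill, conv, y, w) {
  solve1 <- function(b, y) max(0, sum(w * b * y) / max(sum(w * b * b), 1e-300))
  a11 <- sum(w * spill^2); a12 <- sum(w * spill * conv); a22 <- sum(w * conv^2)
  b1 <- sum(w * spill * y); b2 <- sum(w * conv * y)
  det <- a11 * a22 - a12^2
  if (det > 1e-12 * max(a11 * a22, 1e-300)) {
    isf <- (b1 * a22 - b2 * a12) / det
    qin <- (b2 * a11 - b1 * a12) / det
  } else {
    isf <- 0; qin <- solve1(conv, y)
  }
  if (isf < 0 || isf > 1 || qin < 0) {
    # try the active-set corners and keep the best feasible one
    cands <- list(c(0, solve1(conv, y)),
                  c(min(max(solve1(spill, y - solve1(conv, y) * conv), 0), 1),
                    solve1(conv, y)),
                  c(min(max(solve1(spill, y), 0), 1), 0),
                  c(1, solve1(conv, y - spill)))
    rss <- vapply(cands, function(p)
      sum(w * (y - p[1L] * spill - p[2L] * conv)^2), numeric(1L))
    best <- cands[[which.min(rss)]]
    isf <- best[1L]; qin <- best[2L]
  }
  c(isf = isf, qin = qin)
}

#' Fit the phantom one-tissue model to measured TACs
#'
#' Minimises the frame-duration-weighted residual sum of squares between the
#' tissue TAC and the forward model. For fixed `(delay, qout)` the model is
#' linear in `(qin, isf)`, so those are profiled out in closed form (with
#' their box constraints); `qout` is then optimised in one dimension per
#' delay on a coarse delay grid, and the best delay is refined continuously.
#' The procedure is fully deterministic.
#'
#' @param input_tac,tissue_tac Decay-corrected [sampled_tac()]s sharing one
#'   schedule.
#' @param vcyl_ml Exchange-cylinder volume (ml) used to convert rates to
#'   flows.
#' @param delay_grid Candidate delays (s), default 0-30 s in 1 s steps.
#' @param qout_bounds,qin_max Rate-constant bounds (min^-1).
#' @param isf_scaling,input_interp,time_step Passed to the forward model.
#' @param half_life_s Half-life (s) used to emulate the decay-corrected
#'   acquisition in the frame predictions and input reconstruction
#'   (default 15O); `Inf` disables the decay weighting.
#' @param refine_delay Continuously refine the delay around the best grid
#'   point (default TRUE).
#' @return A `kinetic_fit`: fitted `qin_min`, `qout_min`, `isf`, `delay_s`,
#'   converted `Qin_ml_min`/`Qout_ml_min`, weighted `rss`, `converged`,
#'   `n_function_evals`, approximate standard errors `se`, and a
#'   `low_signal` flag (tissue indistinguishable from zero).
#' @export
fit_model <- function(input_tac, tissue_tac, vcyl_ml = 160,
                      delay_grid = seq(0, 30, by = 1),
                      qout_bounds = c(0, 10), qin_max = 10,
                      isf_scaling = c("none", "one-minus-isf"),
                      input_interp = "integral-spline",
                      time_step = 0.1, half_life_s = O15_HALF_LIFE_S,
                      refine_delay = TRUE) {
  isf_scaling <- match.arg(isf_scaling)
  stop_if(!inherits(input_tac, "sampled_tac") || !inherits(tissue_tac, "sampled_tac"),
          "input_tac and tissue_tac must be sampled_tac objects")
  stop_if(!schedules_equal(input_tac$schedule, tissue_tac$schedule),
          "input and tissue TACs must share one schedule")
  stop_if(!input_tac$decay_corrected || !tissue_tac$decay_corrected,
          "both TACs must be decay-corrected before fitting")
  stop_if(vcyl_ml <= 0, "vcyl must be positive")

  schedule <- tissue_tac$schedule
  y <- tissue_tac$values
  w <- schedule$frame_durations
  input <- reconstruct_input(input_tac, input_interp, half_life_s, time_step)
  t_end <- max(frame_ends(schedule))
  n_steps <- max(2L, ceiling(t_end / time_step))
  grid <- seq(0, t_end, length.out = n_steps + 1L)
  avg_mat <- frame_average_matrix(grid, schedule)
  # measurement-consistent frame prediction: decay, average, decay-correct
  if (is.finite(half_life_s) && !is.null(avg_mat)) {
    lambda <- log(2) / half_life_s
    dfac <- frame_decay_factors(schedule, half_life_s, tissue_tac$reference_time)
    avg_mat <- sweep(avg_mat, 2L, exp(-lambda * (grid - tissue_tac$reference_time)), `*`) / dfac
  }
  n_eval <- 0L

  low_signal <- max(abs(y)) < 1e-9 * max(abs(input_tac$values), 1e-300)

  f_avg <- function(values) {
    if (is.null(avg_mat)) frame_average(grid, values, schedule)
    else drop(avg_mat %*% values)
  }
  shifted_input <- function(delay_s) {
    g <- stats::approx(input$time + delay_s, input$values, xout = grid,
                       yleft = 0, rule = 2)$y
    list(g = g, spill = f_avg(g))
  }

  profile_rss <- function(cache, qout_min) {
    n_eval <<- n_eval + 1L
    conv <- min_to_s(1) * f_avg(conv_exp(grid, cache$g, min_to_s(qout_min)))
    coefs <- solve_linear_pair(cache$spill, conv, y, w)
    qin <- min(coefs[["qin"]], qin_max)
    isf <- coefs[["isf"]]
    scale <- if (isf_scaling == "one-minus-isf") (1 - isf) else 1
    # with the (1-isf) variant the profiled coefficient absorbs the scale
    if (isf_scaling == "one-minus-isf" && scale > 1e-12) qin <- min(qin / scale, qin_max)
    fitted <- isf * cache$spill + scale * qin * conv
    list(rss = sum(w * (y - fitted)^2), qin_min = qin, isf = isf)
  }

  best_for_delay <- function(delay_s, tol = 1e-6) {
    cache <- shifted_input(delay_s)
    opt <- stats::optimize(function(q) profile_rss(cache, q)$rss,
                           lower = qout_bounds[1L], upper = qout_bounds[2L],
                           tol = tol)
    list(delay_s = delay_s, qout_min = opt$minimum, rss = opt$objective)
  }

  fits <- lapply(delay_grid, best_for_delay)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1L), "rss"))]]
  if (refine_delay && length(delay_grid) > 1L) {
    step <- min(diff(sort(delay_grid)))
    lo <- max(min(delay_grid), best$delay_s - step)
    hi <- min(max(delay_grid), best$delay_s + step)
    ref <- stats::optimize(function(d) best_for_delay(d)$rss,
                           lower = lo, upper = hi, tol = 1e-4)
    if (ref$objective < best$rss) best$delay_s <- ref$minimum
  }
  best <- best_for_delay(best$delay_s, tol = 1e-9)
  final <- profile_rss(shifted_input(best$delay_s), best$qout_min)
  params <- list(qin_min = final$qin_min, qout_min = best$qout_min,
                 isf = final$isf, delay_s = best$delay_s)
  converged <- is.finite(final$rss)

  se <- fit_standard_errors(params, input, schedule, y, w, isf_scaling,
                            time_step, half_life_s, final$rss)
  structure(c(params,
              list(Qin_ml_min = to_flow(params$qin_min, vcyl_ml),
                   Qout_ml_min = to_flow(params$qout_min, vcyl_ml),
                   vcyl_ml = vcyl_ml, rss = final$rss, converged = converged,
                   n_function_evals = n_eval, se = se,
                   low_signal = low_signal, isf_scaling = isf_scaling)),
            class = "kinetic_fit")
}

# Approximate standard errors via the Gauss-Newton covariance
# sigma^2 (J' W J)^-1 with a forward-difference Jacobian; NA when the
# information matrix is singular (e.g. a parameter at its bound).
fit_standard_errors <- function(params, input, schedule, y, w, isf_scaling,
                                time_step, half_life_s, rss) {
  pred <- function(p) {
    forward_model(list(qin_min = p[1L], qout_min = p[2L], isf = p[3L],
                       delay_s = max(p[4L], 0)),
                  input, schedule = schedule, isf_scaling = isf_scaling,
                  time_step = time_step, half_life_s = half_life_s)$values
  }
  p0 <- c(params$qin_min, params$qout_min, params$isf, params$delay_s)
  out <- rep(NA_real_, 4L)
  names(out) <- c("qin_min", "qout_min", "isf", "delay_s")
  res <- try({
    f0 <- pred(p0)
    J <- vapply(seq_along(p0), function(i) {
      h <- max(1e-5, 1e-5 * abs(p0[i]))
      pi <- p0; pi[i] <- pi[i] + h
      (pred(pi) - f0) / h
    }, numeric(length(y)))
    info <- crossprod(J, w * J)
    dof <- max(length(y) - length(p0), 1L)
    sigma2 <- rss / dof
    cov <- try(solve(info) * sigma2, silent = TRUE)
    if (!inherits(cov, "try-error")) out <- sqrt(pmax(diag(cov), 0))
    out
  }, silent = TRUE)
  if (inherits(res, "try-error")) out else res
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic_fit> Qin %.4g ml/min, Qout %.4g ml/min (Vcyl %g ml)\n",
              x$Qin_ml_min, x$Qout_ml_min, x$vcyl_ml))
  cat(sprintf("  qin %.5g min^-1, qout %.5g min^-1, isf %.4g, delay %.4g s\n",
              x$qin_min, x$qout_min, x$isf, x$delay_s))
  cat(sprintf("  weighted RSS %.6g, %d model evaluations, converged: %s%s\n",
              x$rss, x$n_function_evals, x$converged,
              if (isTRUE(x$low_signal)) " [low signal]" else ""))
  invisible(x)
}

#' @export
coef.kinetic_fit <- function(object, ...) {
  c(qin_min = object$qin_min, qout_min = object$qout_min,
    isf = object$isf, delay_s = object$delay_s)
}

#' @export
as.data.frame.kinetic_fit <- function(x, ...) {
  data.frame(qin_min = x$qin_min, qout_min = x$qout_min, isf = x$isf,
             delay_s = x$delay_s, Qin_ml_min = x$Qin_ml_min,
             Qout_ml_min = x$Qout_ml_min, vcyl_ml = x$vcyl_ml, rss = x$rss,
             converged = x$converged, low_signal = x$low_signal)
}
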