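test_that("decay correction uses the exact frame-averaged factor", {
  # near-instantaneous frame one half-life after injection: factor -> 1/2
  sch <- frame_schedule(122.24, 1e-6)
  tac <- sampled_tac(sch, 100)
  expect_equal(decay_correct(tac, 122.24, "apply")$values, 200, tolerance = 1e-6)

  # infinite half-life is the identity
  sch24 <- default_frame_schedule()
  set.seed(2)
  tac24 <- sampled_tac(sch24, stats::runif(24, 1, 100))
  expect_equal(decay_correct(tac24, Inf, "apply")$values, tac24$values)

  # frame-averaged factor, not the midpoint factor, on a long frame
  long <- frame_schedule(0, 120)
  lam <- log(2) / 122.24
  expected <- (1 - exp(-lam * 120)) / (lam * 120)
  expect_equal(decay_correct(sampled_tac(long, 1), 122.24, "apply")$values,
               1 / expected)
})

test_that("apply and remove are exact inverses and refuse double application", {
  sch <- default_frame_schedule()
  set.seed(3)
  tac <- sampled_tac(sch, stats::runif(24, 0.1, 500))
  round_trip <- decay_correct(decay_correct(tac, direction = "apply"),
                              direction = "remove")
  expect_lt(max(abs(round_trip$values - tac$values) / tac$values), 1e-9)
  expect_false(round_trip$decay_corrected)
  expect_error(decay_correct(decay_correct(tac, direction = "apply"),
                             direction = "apply"), "already")
  expect_error(decay_correct(tac, direction = "remove"), "not decay-corrected")
})

test_that("forward model limits match closed forms", {
  tt <- seq(0, 300, by = 0.1)
  input <- continuous_curve(tt, gamma_curve(tt))
  eval_t <- seq(0, 280, by = 5)

  null <- forward_model(list(qin_min = 0, qout_min = 0.5, isf = 0, delay_s = 0),
                        input, times = eval_t)
  expect_equal(max(abs(null$values)), 0)

  spill <- forward_model(list(qin_min = 0, qout_min = 0.5, isf = 1, delay_s = 0),
                         input, times = eval_t)
  expect_equal(spill$values, gamma_curve(eval_t), tolerance = 1e-9)

  # constant input, delay 0: steady state c (isf + qin/qout)
  const <- continuous_curve(seq(0, 5000, 1), rep(4, 5001))
  ss <- forward_model(list(qin_min = 0.4, qout_min = 0.8, isf = 0.2, delay_s = 0),
                      const, times = 5000, time_step = 0.5)
  expect_equal(ss$values, 4 * (0.2 + 0.4 / 0.8), tolerance = 1e-3)
})

test_that("analytic convolution matches a brute-force Riemann sum", {
  tt <- seq(0, 120, by = 0.1)
  input <- continuous_curve(tt, gamma_curve(tt))
  p <- list(qin_min = 0.7, qout_min = 0.9, isf = 0.15, delay_s = 4)
  eval_t <- c(20, 45, 90, 118)
  model <- forward_model(p, input, times = eval_t)

  brute <- vapply(eval_t, function(t_i) {
    s <- seq(0, t_i, by = 0.01)
    cin_d <- stats::approx(tt + p$delay_s, input$values, xout = s,
                           yleft = 0, rule = 2)$y
    integrand <- cin_d * exp(-p$qout_min / 60 * (t_i - s))
    conv <- sum((integrand[-1L] + integrand[-length(s)]) / 2 * diff(s))
    cin_at_t <- stats::approx(tt + p$delay_s, input$values, xout = t_i,
                              yleft = 0, rule = 2)$y
    p$isf * cin_at_t + p$qin_min / 60 * conv
  }, numeric(1L))
  expect_lt(max(abs(model$values - brute) / abs(brute)), 5e-4)
})

test_that("rate constants convert to flows by the cylinder volume", {
  expect_equal(to_flow(0.625, 160), 100)
  expect_equal(to_flow(0, 160), 0)
  expect_equal(to_flow(1.0, 160), 160)
  expect_error(to_flow(1, 0), "positive")
})

test_that("noiseless simulated measurements are recovered within 1%", {
  case <- ref_case()
  fit <- fit_model(case$input_tac, case$tissue_tac)
  expect_true(fit$converged)
  expect_lt(abs(fit$qin_min - 0.625) / 0.625, 0.01)
  expect_lt(abs(fit$qout_min - 0.625) / 0.625, 0.01)
  expect_lt(abs(fit$isf - 0.1), 0.01)
  expect_lt(abs(fit$delay_s - 5), 0.5)
  expect_equal(fit$Qin_ml_min, fit$qin_min * 160)
  expect_equal(fit$Qout_ml_min, fit$qout_min * 160)
})

test_that("pure spill-over data fit to qin ~ 0 with the isf recovered", {
  case <- ref_case()
  tissue <- sampled_tac(case$schedule, 0.25 * case$input_tac$values,
                        decay_corrected = TRUE)
  fit <- fit_model(case$input_tac, tissue, delay_grid = seq(0, 10, 1))
  expect_lt(fit$qin_min, 0.01)
  expect_equal(fit$isf, 0.25, tolerance = 0.01)
})

test_that("fitting is deterministic and scale-invariant", {
  case <- ref_case()
  f1 <- fit_model(case$input_tac, case$tissue_tac)
  f2 <- fit_model(case$input_tac, case$tissue_tac)
  expect_identical(coef(f1), coef(f2))

  k <- 3.7  # rescaling both TACs leaves the rate constants unchanged
  scale_tac <- function(tac) sampled_tac(tac$schedule, k * tac$values,
                                         decay_corrected = TRUE)
  f3 <- fit_model(scale_tac(case$input_tac), scale_tac(case$tissue_tac))
  expect_equal(f3$Qin_ml_min, f1$Qin_ml_min, tolerance = 1e-6)
  expect_equal(f3$Qout_ml_min, f1$Qout_ml_min, tolerance = 1e-6)
})

test_that("fit input contracts are enforced", {
  case <- ref_case()
  other <- build_frame_schedule(list(c(28, 10)))
  expect_error(fit_model(case$input_tac,
                         sampled_tac(other, rep(1, 28), decay_corrected = TRUE)),
               "schedule")
  raw <- decay_correct(case$tissue_tac, direction = "remove")
  expect_error(fit_model(case$input_tac, raw), "decay-corrected")

  zero <- sampled_tac(case$schedule, rep(0, 24), decay_corrected = TRUE)
  fit <- fit_model(case$input_tac, zero, delay_grid = c(0, 5))
  expect_true(fit$converged)
  expect_true(fit$low_signal)
  expect_lt(fit$qin_min, 1e-6)
})

test_that("parameters are identifiable across the studied flow range", {
  # spot checks at the extremes of the Qref range; the full factorial grid
  # runs in the acceptance suite
  sch <- default_frame_schedule()
  for (qref in c(30, 200)) {
    set <- phantom_settings(250, qref / 250,
                            qcyl_measured_pre = qref, qcyl_measured_post = qref)
    truth <- ideal_ground_truth(set, isf = 0.1, delay_s = 5)
    sim <- simulate_phantom(set, truth, generate_bolus(500))
    fit <- fit_model(decay_correct(sample_frames(sim$input, sch), direction = "apply"),
                     decay_correct(sample_frames(sim$tissue, sch), direction = "apply"))
    expect_lt(abs(fit$Qin_ml_min - qref) / qref, 0.01)
    expect_lt(abs(fit$Qout_ml_min - qref) / qref, 0.01)
  }
})
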