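test_that("single-pass transport conserves the injected activity", {
  case <- ref_case()
  sim <- simulate_phantom(case$settings, case$truth, case$bolus,
                          half_life_s = Inf, duration_s = 600)
  mb <- mass_balance(sim)
  expect_lt(abs(mb$relative_imbalance), 0.005)
  # decay-corrected bookkeeping balances with decay on as well
  mb2 <- mass_balance(case$sim)
  expect_lt(abs(mb2$relative_imbalance), 0.005)
})

test_that("simulator agrees with an independent stiff ODE integration", {
  skip_if_not_installed("deSolve")
  case <- ref_case()
  s <- case$settings; tr <- case$truth; bol <- case$bolus
  f_pump <- s$qpump_ml_min / 60
  rate_fun <- stats::approxfun(bol$time, 1000 * bol$activity_rate,
                               yleft = 0, yright = 0)
  tt <- seq(0, 280, by = 1)
  tt_fine <- seq(0, 280, by = 0.25)
  # stage 1: input chamber alone (decay-corrected units)
  chamber <- deSolve::lsoda(c(a_in = 0), tt_fine, function(t, y, p)
    list(rate_fun(t) - f_pump / s$v_input_ml * y[1L]),
    NULL, rtol = 1e-10, atol = 1e-8)
  cin_fun <- stats::approxfun(tt_fine, chamber[, "a_in"] / s$v_input_ml, rule = 2)
  # stage 2: exchange cylinder driven by the oracle's own delayed input
  tissue <- deSolve::lsoda(c(c_tis = 0), tt, function(t, y, p) {
    cin_del <- if (t < tr$delay_s) 0 else cin_fun(t - tr$delay_s)
    list(tr$qin_min / 60 * cin_del - tr$qout_min / 60 * y[1L])
  }, NULL, rtol = 1e-10, atol = 1e-8)
  decay <- exp(-log(2) / 122.24 * tt)
  cin_ode <- cin_fun(tt) * decay
  cin_del <- ifelse(tt < tr$delay_s, 0, cin_fun(pmax(tt - tr$delay_s, 0)))
  tis_ode <- (tissue[, "c_tis"] + tr$isf * cin_del) * decay

  cin_sim <- stats::approx(case$sim$input$time, case$sim$input$values, tt)$y
  tis_sim <- stats::approx(case$sim$tissue$time, case$sim$tissue$values, tt)$y
  scale_in <- max(abs(cin_ode)); scale_tis <- max(abs(tis_ode))
  expect_lt(max(abs(cin_sim - cin_ode)) / scale_in, 1e-3)
  expect_lt(max(abs(tis_sim - tis_ode)) / scale_tis, 1e-3)
})

test_that("no inflow and no spill-over yields a zero tissue curve", {
  case <- ref_case()
  truth0 <- ground_truth(0, 0.5, isf = 0, delay_s = 5)
  sim <- simulate_phantom(case$settings, truth0, case$bolus)
  expect_equal(max(abs(sim$tissue$values)), 0)
})

test_that("faster washout strictly lowers the tissue tail", {
  case <- ref_case()
  tails <- vapply(c(0.3, 0.6, 1.2), function(qout) {
    sim <- simulate_phantom(case$settings,
                            ground_truth(0.625, qout, isf = 0, delay_s = 5),
                            case$bolus)
    sim$tissue$values[length(sim$tissue$values)]
  }, numeric(1L))
  expect_true(all(diff(tails) < 0))
})

test_that("unphysical phantom configurations are refused", {
  expect_error(phantom_settings(0, 0.4), "positive")
  expect_error(phantom_settings(200, 1.4), "constriction")
  expect_error(phantom_settings(200, 0.4, vcyl_ml = 0), "positive")
  expect_error(ground_truth(-1, 0.5), "nonnegative")
  case <- ref_case()
  expect_warning(
    simulate_phantom(phantom_settings(100, 0.5),
                     ground_truth(1.0, 1.0), case$bolus),
    "pump flow")
})

test_that("frame noise is seeded, scaled and zero at scale 0", {
  case <- ref_case()
  tac <- sample_frames(case$sim$tissue, case$schedule)
  expect_identical(add_noise(tac, 0), tac)
  a <- add_noise(tac, 0.5, seed = 11)
  expect_identical(a, add_noise(tac, 0.5, seed = 11))
  expect_false(identical(a$values, add_noise(tac, 0.5, seed = 12)$values))

  # Monte-Carlo check of the frame-variance model on a single frame
  k <- 20L
  dfac <- (function(s, hl, t0) {
    lam <- log(2) / hl
    t1 <- s$frame_starts - t0; t2 <- t1 + s$frame_durations
    (exp(-lam * t1) - exp(-lam * t2)) / (lam * s$frame_durations)
  })(case$schedule, 122.24, 0)
  expected_sd <- 0.5 * sqrt(max(tac$values[k], 1e-3) /
                              (case$schedule$frame_durations[k] * dfac[k]))
  reps <- vapply(seq_len(1000), function(s)
    add_noise(tac, 0.5, seed = s)$values[k], numeric(1L))
  expect_equal(stats::sd(reps), expected_sd, tolerance = 0.1)
})

test_that("voxel rendering and VOI extraction round-trip the TACs", {
  case <- ref_case()
  input_tac <- sample_frames(case$sim$input, case$schedule)
  tissue_tac <- sample_frames(case$sim$tissue, case$schedule)
  dims <- c(16L, 16L, 8L)
  m_in <- cylinder_mask(dims, center = c(5, 8), radius = 2)
  m_tis <- cylinder_mask(dims, center = c(12, 8), radius = 3)
  vol <- render_volume_series(input_tac, tissue_tac, m_in, m_tis)
  expect_equal(extract_voi_tac(vol, m_in)$values, input_tac$values)
  expect_equal(extract_voi_tac(vol, m_tis)$values, tissue_tac$values)

  # mean over a uniform region is mask-size invariant
  one_voxel <- array(FALSE, dims)
  one_voxel[which(m_tis)[1L]] <- TRUE
  expect_equal(extract_voi_tac(vol, one_voxel)$values, tissue_tac$values)

  expect_error(render_volume_series(input_tac, tissue_tac, m_in, m_in),
               "disjoint")
  expect_error(extract_voi_tac(vol, array(FALSE, dims)), "empty")
})
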