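#' Flow-phantom configuration
#'
#' Pump/constriction configuration of the flow phantom together with the
#' flow-meter readings and chamber volumes. The phantom pumps water at
#' `qpump` through an input chamber (left-ventricle surrogate, volume
#' `v_input_ml`) into an exchange cylinder (myocardium surrogate, volume
#' `vcyl_ml`); constrictor valves split the flow between the cylinder
#' (`qcyl`) and the perforated tube bypass (`qtube`). The reference flow
#' `Qref` is derived from the calibrated cylinder flow-meter readings taken
#' before and after a measurement.
#'
#' @param qpump_ml_min Set pump flow (ml/min), > 0.
#' @param constriction_fraction Fraction of `qpump` directed through the
#'   exchange cylinder, in (0, 1); the study protocol used 0.2/0.4/0.6/0.8.
#' @param qcyl_nominal,qtube_nominal Nominal split flows (ml/min); default
#'   to `constriction_fraction * qpump` and the remainder.
#' @param qcyl_measured_pre,qcyl_measured_post Flow-meter readings for the
#'   cylinder branch before/after the measurement (ml/min); default nominal.
#' @param qtube_measured_pre,qtube_measured_post Same for the tube branch.
#' @param vcyl_ml Exchange-cylinder volume (ml), default 160.
#' @param v_input_ml Input-chamber volume (ml), default 15.7.
#' @param flowmeter_calibration Multiplicative flow-meter calibration factor
#'   applied when deriving `Qref` (default 1).
#' @return An object of class `phantom_settings`.
#' @seealso [qref_ml_min()], [ground_truth()], [simulate_phantom()]
#' @export
phantom_settings <- function(qpump_ml_min, constriction_fraction,
                             qcyl_nominal = constriction_fraction * qpump_ml_min,
                             qtube_nominal = qpump_ml_min - qcyl_nominal,
                             qcyl_measured_pre = qcyl_nominal,
                             qcyl_measured_post = qcyl_nominal,
                             qtube_measured_pre = qtube_nominal,
                             qtube_measured_post = qtube_nominal,
                             vcyl_ml = 160, v_input_ml = 15.7,
                             flowmeter_calibration = 1) {
  stop_if(qpump_ml_min <= 0, "qpump must be positive")
  stop_if(constriction_fraction <= 0 || constriction_fraction >= 1,
          "constriction_fraction must be in (0, 1)")
  stop_if(vcyl_ml <= 0 || v_input_ml <= 0, "chamber volumes must be positive")
  stop_if(flowmeter_calibration <= 0, "flowmeter_calibration must be positive")
  flows <- c(qcyl_nominal, qtube_nominal, qcyl_measured_pre, qcyl_measured_post,
             qtube_measured_pre, qtube_measured_post)
  stop_if(any(flows <= 0), "all flows must be positive")
  structure(list(qpump_ml_min = qpump_ml_min,
                 constriction_fraction = constriction_fraction,
                 qcyl_nominal = qcyl_nominal, qtube_nominal = qtube_nominal,
                 qcyl_measured_pre = qcyl_measured_pre,
                 qcyl_measured_post = qcyl_measured_post,
                 qtube_measured_pre = qtube_measured_pre,
                 qtube_measured_post = qtube_measured_post,
                 vcyl_ml = vcyl_ml, v_input_ml = v_input_ml,
                 flowmeter_calibration = flowmeter_calibration),
            class = "phantom_settings")
}

#' @export
print.phantom_settings <- function(x, ...) {
  cat(sprintf("<phantom_settings> Qpump %g ml/min, constriction %.0f%%, Qref %.4g ml/min (Vcyl %g ml, Vin %g ml)\n",
              x$qpump_ml_min, 100 * x$constriction_fraction, qref_ml_min(x),
              x$vcyl_ml, x$v_input_ml))
  invisible(x)
}

#' Reference flow derived from cylinder flow-meter readings
#'
#' `Qref = flowmeter_calibration x mean(pre, post Qcyl readings)` (ml/min).
#' @param settings A [phantom_settings()].
#' @export
qref_ml_min <- function(settings) {
  settings$flowmeter_calibration *
    mean(c(settings$qcyl_measured_pre, settings$qcyl_measured_post))
}

#' Ground-truth kinetic parameters for a simulated measurement
#'
#' @param qin_min,qout_min Inflow/washout rate constants (min^-1), >= 0.
#' @param isf Input signal fraction (spill-over of the input-chamber signal
#'   into the cylinder region), in \[0, 1\].
#' @param delay_s Transit delay from input chamber to perforated tube (s).
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(qin_min, qout_min, isf = 0.1, delay_s = 5) {
  stop_if(qin_min < 0 || qout_min < 0, "rate constants must be nonnegative")
  stop_if(isf < 0 || isf > 1, "isf must be in [0, 1]")
  stop_if(delay_s < 0, "delay must be nonnegative")
  structure(list(qin_min = qin_min, qout_min = qout_min,
                 isf = isf, delay_s = delay_s),
            class = "ground_truth")
}

#' Ideal ground truth for a phantom configuration
#'
#' For an ideal measurement the modelled flows equal the reference flow:
#' `qin = qout = Qref / Vcyl`.
#' @param settings A [phantom_settings()].
#' @inheritParams ground_truth
#' @export
ideal_ground_truth <- function(settings, isf = 0.1, delay_s = 5) {
  rate <- qref_ml_min(settings) / settings$vcyl_ml
  ground_truth(rate, rate, isf = isf, delay_s = delay_s)
}

#' Simulate the flow-phantom experiment
#'
#' Digital twin of one phantom measurement. The injected bolus feeds a
#' well-mixed input chamber flushed at the pump flow; the exchange cylinder
#' is a one-tissue compartment driven by the delayed input-chamber
#' concentration at rate `qin` with washout `qout`. The curve measured over
#' the cylinder region additionally contains a spill-over fraction `isf` of
#' the (delayed) input signal. Physical (non-decay-corrected) curves include
#' radioactive decay; transport is single-pass (no recirculation), so with
#' `half_life_s = Inf` activity is conserved between the chambers and the
#' cumulative outflow.
#'
#' Both compartment equations are linear first-order ODEs with
#' piecewise-linear driving terms and are integrated exactly per time step
#' with an exponential integrator.
#'
#' @param settings A [phantom_settings()].
#' @param truth A [ground_truth()].
#' @param bolus A [generate_bolus()] record.
#' @param half_life_s Radionuclide half-life (s); default 15O (122.24 s);
#'   `Inf` disables decay.
#' @param time_step Integration step (s), default 0.1.
#' @param duration_s Simulated span (s), default 300 (covers the 280 s scan).
#' @return A `phantom_simulation`: list with [continuous_curve()]s `input`
#'   (input-chamber concentration) and `tissue` (measured cylinder curve
#'   including spill-over), plus `tissue_compartment` (cylinder compartment
#'   concentration without spill-over), and the inputs used.
#' @export
simulate_phantom <- function(settings, truth, bolus,
                             half_life_s = O15_HALF_LIFE_S,
                             time_step = 0.1, duration_s = 300) {
  stop_if(!inherits(settings, "phantom_settings"), "settings must be phantom_settings")
  stop_if(!inherits(truth, "ground_truth"), "truth must be a ground_truth")
  stop_if(!inherits(bolus, "bolus_record"), "bolus must be a bolus_record")
  stop_if(half_life_s <= 0, "half-life must be positive")
  lambda <- log(2) / half_life_s
  f_pump <- settings$qpump_ml_min / 60                  # ml/s
  qin_s <- min_to_s(truth$qin_min)
  qout_s <- min_to_s(truth$qout_min)
  if (truth$qin_min * settings$vcyl_ml > settings$qpump_ml_min + 1e-9)
    warning("qin x Vcyl exceeds the pump flow; configuration is unphysical",
            call. = FALSE)

  time <- seq(0, duration_s, by = time_step)
  rate_kBq_s <- 1000 * stats::approx(bolus$time, bolus$activity_rate,
                                     xout = time, yleft = 0, yright = 0, rule = 2)$y
  # Transport is solved in decay-corrected (injection-referenced) units, in
  # which activity is conserved; radioactive decay is applied to the
  # measured signals afterwards. This matches the kinetic-analysis
  # convention that the one-tissue model holds exactly for decay-corrected
  # TACs, with the dispensed activity reported decay-corrected to the
  # injection time.
  # input chamber activity A* (kBq): A*' = b(t) - (F/Vin) A*
  a_in <- linear_decay_ode(time, rate_kBq_s, f_pump / settings$v_input_ml)
  c_in <- a_in / settings$v_input_ml                    # kBq/ml
  # delayed input concentration on the same grid (zero before the delay)
  c_in_delayed <- stats::approx(time + truth$delay_s, c_in, xout = time,
                                yleft = 0, rule = 2)$y
  # cylinder compartment: C*' = qin C_in*(t - delay) - qout C*
  c_tis <- linear_decay_ode(time, qin_s * c_in_delayed, qout_s)
  decay <- exp(-lambda * time)
  measured <- (c_tis + truth$isf * c_in_delayed) * decay

  structure(list(input = continuous_curve(time, c_in * decay),
                 tissue = continuous_curve(time, measured),
                 tissue_compartment = continuous_curve(time, c_tis * decay),
                 settings = settings, truth = truth, bolus = bolus,
                 half_life_s = half_life_s),
            class = "phantom_simulation")
}

#' @export
print.phantom_simulation <- function(x, ...) {
  cat(sprintf("<phantom_simulation> Qref %.4g ml/min, truth qin %.4g / qout %.4g min^-1, isf %.3g, delay %.3g s\n",
              qref_ml_min(x$settings), x$truth$qin_min, x$truth$qout_min,
              x$truth$isf, x$truth$delay_s))
  print(x$input); print(x$tissue)
  invisible(x)
}

#' Activity bookkeeping for a simulated measurement
#'
#' Splits the injected activity into residual chamber and delay-line
#' contents and cumulative single-pass outflow at the end of the
#' simulation, in decay-corrected units (in which activity is conserved):
#' injected = residual + outflow.
#'
#' @param sim A `phantom_simulation`.
#' @return List with `injected_kBq`, `residual_kBq`, `outflow_kBq` and
#'   `relative_imbalance`.
#' @export
mass_balance <- function(sim) {
  stop_if(!inherits(sim, "phantom_simulation"), "sim must be a phantom_simulation")
  s <- sim$settings
  t <- sim$input$time
  f_pump <- s$qpump_ml_min / 60
  qin_s <- min_to_s(sim$truth$qin_min)
  qout_s <- min_to_s(sim$truth$qout_min)
  undecay <- exp(log(2) / sim$half_life_s * t)
  c_in <- sim$input$values * undecay
  c_tis <- sim$tissue_compartment$values * undecay
  c_in_delayed <- stats::approx(t + sim$truth$delay_s, c_in, xout = t,
                                yleft = 0, rule = 2)$y
  # what leaves the chamber arrives at the tube one delay later and splits
  # into cylinder uptake and bypass; the cylinder washes out at qout.
  bypass <- (f_pump - qin_s * s$vcyl_ml) * c_in_delayed
  washout <- qout_s * s$vcyl_ml * c_tis
  outflow <- pwl_integral(t, bypass + washout, t[1L], t[length(t)])
  residual <- c_in[length(t)] * s$v_input_ml + c_tis[length(t)] * s$vcyl_ml +
    # activity in transit inside the delay line
    f_pump * pwl_integral(t, c_in, max(t[length(t)] - sim$truth$delay_s, 0), t[length(t)])
  injected <- 1000 * sim$bolus$injected_MBq
  list(injected_kBq = injected, residual_kBq = residual, outflow_kBq = outflow,
       relative_imbalance = (injected - residual - outflow) / injected)
}

#' Add frame-dependent measurement noise to a sampled TAC
#'
#' Gaussian noise with standard deviation
#' `noise_scale * sqrt(max(value, eps) / (duration x decay_factor))`, the
#' standard variance approximation for dynamic PET frames: variance scales
#' with the count rate and inversely with frame duration and the remaining
#' (decayed) signal.
#'
#' @param tac A [sampled_tac()].
#' @param noise_scale Nonnegative scale; 0 returns the input unchanged.
#' @param half_life_s Half-life used for the frame decay factors (s).
#' @param seed Optional integer seed for bit-reproducible noise.
#' @param eps Floor applied to the value inside the square root (kBq/ml).
#' @return A [sampled_tac()] with perturbed values.
#' @export
add_noise <- function(tac, noise_scale, half_life_s = O15_HALF_LIFE_S,
                      seed = NULL, eps = 1e-3) {
  stop_if(!inherits(tac, "sampled_tac"), "tac must be a sampled_tac")
  stop_if(noise_scale < 0, "noise_scale must be nonnegative")
  if (noise_scale == 0) return(tac)
  dfac <- frame_decay_factors(tac$schedule, half_life_s, tac$reference_time)
  sdev <- noise_scale * sqrt(pmax(tac$values, eps) /
                               (tac$schedule$frame_durations * dfac))
  noisy <- with_local_seed(seed, stats::rnorm(n_frames(tac$schedule), 0, sdev))
  sampled_tac(tac$schedule, tac$values + noisy,
              decay_corrected = tac$decay_corrected,
              reference_time = tac$reference_time)
}

#' Render TACs into a 4D voxel volume and extract them back
#'
#' `render_volume_series()` paints the input and tissue TAC values uniformly
#' into two disjoint voxel masks of a 3D grid, one 3D volume per frame —
#' a minimal stand-in for a reconstructed dynamic series.
#' `extract_voi_tac()` averages the voxels of a mask per frame, the
#' volume-of-interest operation used to obtain TACs from images.
#'
#' @param input_tac,tissue_tac [sampled_tac()]s on a common schedule.
#' @param input_mask,tissue_mask Logical 3D arrays of identical dimension,
#'   non-empty and disjoint; see [cylinder_mask()].
#' @return A `volume_series`: list with the 4D `data` array
#'   (x, y, z, frame), both masks, and the schedule.
#' @export
render_volume_series <- function(input_tac, tissue_tac, input_mask, tissue_mask) {
  stop_if(!schedules_equal(input_tac$schedule, tissue_tac$schedule),
          "input and tissue TACs must share one schedule")
  stop_if(!identical(dim(input_mask), dim(tissue_mask)),
          "masks must have identical dimensions")
  stop_if(sum(input_mask) == 0L || sum(tissue_mask) == 0L, "masks must be non-empty")
  stop_if(any(input_mask & tissue_mask), "masks must be disjoint")
  nf <- n_frames(input_tac$schedule)
  vol <- array(0, c(dim(input_mask), nf))
  for (k in seq_len(nf)) {
    frame <- array(0, dim(input_mask))
    frame[input_mask] <- input_tac$values[k]
    frame[tissue_mask] <- tissue_tac$values[k]
    vol[, , , k] <- frame
  }
  structure(list(data = vol, input_mask = input_mask, tissue_mask = tissue_mask,
                 schedule = input_tac$schedule,
                 decay_corrected = input_tac$decay_corrected,
                 reference_time = input_tac$reference_time),
            class = "volume_series")
}

#' @rdname render_volume_series
#' @param volume A `volume_series`.
#' @param mask Logical 3D array selecting the volume of interest.
#' @export
extract_voi_tac <- function(volume, mask) {
  stop_if(!inherits(volume, "volume_series"), "volume must be a volume_series")
  stop_if(!identical(dim(mask), dim(volume$data)[1:3]),
          "mask dimension does not match the volume")
  stop_if(sum(mask) == 0L, "mask is empty")
  vals <- apply(volume$data, 4L, function(frame) mean(frame[mask]))
  sampled_tac(volume$schedule, vals, decay_corrected = volume$decay_corrected,
              reference_time = volume$reference_time)
}

#' Cylindrical voxel mask
#'
#' @param dim Integer grid dimensions c(nx, ny, nz).
#' @param center Cylinder axis position c(x, y) in voxel units.
#' @param radius Cylinder radius in voxels.
#' @param z_range Inclusive axial slice range c(z1, z2).
#' @return A logical 3D array.
#' @export
cylinder_mask <- function(dim, center, radius, z_range = c(1L, dim[3L])) {
  stop_if(radius <= 0, "radius must be positive")
  x <- slice.index(array(0, dim), 1L)
  y <- slice.index(array(0, dim), 2L)
  z <- slice.index(array(0, dim), 3L)
  (x - center[1L])^2 + (y - center[2L])^2 <= radius^2 &
    z >= z_range[1L] & z <= z_range[2L]
}
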