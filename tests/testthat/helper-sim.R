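# Shared noiseless reference case, built once per test run: ideal phantom
# at Qref = 100 ml/min (qin = qout = 0.625 min^-1), isf 0.1, delay 5 s.
ref_settings <- function() {
  phantom_settings(250, 0.4, qcyl_measured_pre = 100, qcyl_measured_post = 100)
}

ref_case <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      settings <- ref_settings()
      truth <- ground_truth(0.625, 0.625, isf = 0.1, delay_s = 5)
      bolus <- generate_bolus(500)
      sim <- simulate_phantom(settings, truth, bolus)
      sch <- default_frame_schedule()
      cache <<- list(
        settings = settings, truth = truth, bolus = bolus, sim = sim,
        schedule = sch,
        input_tac = decay_correct(sample_frames(sim$input, sch), direction = "apply"),
        tissue_tac = decay_correct(sample_frames(sim$tissue, sch), direction = "apply"))
    }
    cache
  }
})

# gamma-variate test curve (smooth, nonnegative, peaked like an input TAC)
gamma_curve <- function(t, amp = 100, onset = 3, alpha = 2, beta = 6) {
  u <- pmax(t - onset, 0)
  amp * u^alpha * exp(-u / beta)
}
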