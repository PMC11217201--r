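# flowphantom

Quality control of quantitative myocardial perfusion PET ([15O]H2O) with a
physical flow phantom, for medical physicists and PET methodologists who
need to separate *technical* sources of flow-value error (injector bolus,
scanner, frame schedule, decay correction, kinetic fit) from biological
variability.

The phantom pumps water at a set flow `Qpump` through an input chamber
(left-ventricle surrogate, 15.7 ml) into an exchange cylinder (myocardium
surrogate, `Vcyl` = 160 ml); constrictor valves split the flow into a
cylinder branch `Qcyl` and a bypass `Qtube`, and the calibrated `Qcyl`
readings define the reference flow `Qref`. The cylinder-region TAC follows
a one-tissue compartment model with spill-over and delay,

    M(t) = ISF * Cin(t - delay) + qin * Int_0^t Cin(s - delay) exp(-qout (t - s)) ds,

with `Qin = qin * Vcyl` and `Qout = qout * Vcyl` (ml/min); for an ideal
measurement `Qin = Qout = Qref`.

The package provides:

* a **digital twin** of one measurement — gamma-variate injector bolus
  calibrated to the dispensed activity, well-mixed chamber transport,
  15O decay, the clinical 24-frame schedule (14x5 s, 3x10 s, 3x20 s,
  4x30 s), frame-dependent noise, and optional 4D voxel rendering with
  VOI extraction (`generate_bolus()`, `simulate_phantom()`,
  `sample_frames()`, `add_noise()`, `render_volume_series()`);
* the **kinetic model and fitter** — analytic convolution forward model,
  exact frame-averaged decay correction, and a deterministic bounded
  weighted least-squares fit with a delay grid search
  (`forward_model()`, `decay_correct()`, `fit_model()`);
* the **repeatability and QC statistics** — flow-value error vs `Qref`,
  test–retest repeatability error, Bland–Altman limits of agreement,
  flow-meter and dispensed-activity QC (`repeatability_error()`,
  `bland_altman()`, `flowmeter_qc()`, `activity_qc()`);
* the **packaged study tables** of a two-system (GE Discovery MI vs
  Siemens Biograph Vision 600), twelve-setting, test–retest phantom study,
  so the published summary statistics recompute offline
  (`load_study_tables()`, `cmd_reproduce_study()`).

## Worked example

Simulate one measurement at `Qref` = 100 ml/min (so the true rates are
`qin = qout = 100/160 = 0.625` min^-1), add realistic frame noise, and fit:

```r
library(flowphantom)

settings <- phantom_settings(qpump_ml_min = 250, constriction_fraction = 0.4,
                             qcyl_measured_pre = 100, qcyl_measured_post = 100)
truth    <- ideal_ground_truth(settings, isf = 0.1, delay_s = 5)
bolus    <- generate_bolus(500, dispense_error_fraction = 0.15, seed = 42)
sim      <- simulate_phantom(settings, truth, bolus)

schedule <- default_frame_schedule()
input  <- decay_correct(add_noise(sample_frames(sim$input,  schedule), 0.5, seed = 1),
                        direction = "apply")
tissue <- decay_correct(add_noise(sample_frames(sim$tissue, schedule), 0.5, seed = 2),
                        direction = "apply")
fit_model(input, tissue)
#> <kinetic_fit> Qin 99.99 ml/min, Qout 99.28 ml/min (Vcyl 160 ml)
#>   qin 0.62492 min^-1, qout 0.62049 min^-1, isf 0.0998, delay 4.942 s
#>   weighted RSS 12930.3, 662 model evaluations, converged: TRUE
```

The fitted `Qin`/`Qout` recover the 100 ml/min ground truth to ~1% under
noise (to ~0.1% without), `isf` and `delay` recover the simulated
spill-over and transit time.

Recompute the published study statistics from the packaged tables:

```r
cmd_reproduce_study()
#> Recomputed study results (packaged tables, offline)
#>   repeatability mean +/- SD: DMI-20 Qin 2.34 +/- 2.85, Qout 3.07 +/- 4.01
#>                              Vision-600 Qin 9.91 +/- 8.42, Qout 11.12 +/- 10.36
#>   between-system mean difference: Qin 1.71 ml/min, Qout -17.33 ml/min
#>   [PASS] activity signed differences reproduce printed column (0)
#>   [PASS] all injected activities within 15% of requested (13.8)
#>   [PASS] flow-meter Qcyl+Qtube vs Qpump within 15% (13.2)
#>   [PASS] DMI-20 repeatability errors all <= 15% (13.26)
#>   [PASS] Vision-600 Qin mean repeatability ~ 10% (9.914)
#>   [PASS] Vision-600 Qout mean repeatability ~ 11% (11.12)
#>   [PASS] Vision-600 errors > 15% in 7 of 24 (7)
```

The Vision-600 system shows ~10%/11% mean test–retest differences with 7
of 24 measurements above the 15% repeatability criterion, while all
DMI-20 measurements stay below it — the technical-reproducibility gap the
phantom protocol is designed to expose.

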