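# insoleGait

Signal processing for optoelectronic pressure-sensitive insoles: from raw
16-channel tactel voltages to vertical ground reaction force (vGRF),
antero-posterior center of pressure (CoP_AP), heel-strike/toe-off gait
events, and a force-plate validation battery — plus a seeded synthetic gait
simulator so the whole chain can be developed and tested without hardware.

## Who this is for

Researchers and engineers working with in-shoe plantar-pressure systems for
real-time gait segmentation (prosthesis/orthosis control, FES triggering,
ambulatory gait assessment) who need a reference implementation of the
standard processing chain and a reproducible way to benchmark it.

## The model

Each *tactel* (an LED-photodiode pair under a deformable silicone frustum)
is a force-to-voltage transducer. After zero-load de-offsetting, load drives
its output voltage negative, and force is recovered with a quartic
calibration polynomial applied piecewise around a noise-floor threshold
V_thresh = -0.01 V:

    F_i = f(V_i) = p1 V^4 + p2 V^3 + p3 V^2 + p4 V + p5   if V_i <= V_thresh
    F_i = 0                                               otherwise

with factory coefficients p = (186.1, 224.5, 64.76, -18.59, 0). The
foot-level variables are

    vGRF    = sum_i F_i
    CoP_AP  = sum_i(F_i w_i AP_i) / sum_i(F_i w_i)   while vGRF >= vGRF_thresh
            = NaN                                     otherwise

where AP_i is each tactel's heel-to-toe coordinate (cm) and w_i = 1/(number
of tactels in the same AP bin) compensates for the clustered sensor
placement. The system detection threshold is vGRF_thresh = 16 f(V_thresh)
= 3.07 N (~3 N). Stance/swing segmentation is a debounced threshold
crossing of the vGRF; the validation battery reports event-timing median
absolute errors, stance-normalized profile correlation/RMSE, repeatability
and body-mass-normalized peaks against a 200 Hz reference device.

## Worked example

```r
library(insoleGait)

cal <- tactel_calibration()
system_force_threshold(cal, 16)
#> [1] 3.074454

cfg   <- gait_sim_config(n_strides = 5, seed = 1)   # 66.2 kg walker, 1.1 s strides
trial <- simulate_trial(cfg)
sig   <- process_stream(trial$insole, trial$cal, trial$layout)
detect_events(sig)
#>   stride_idx hs_time to_time stance_duration stride_time stance_fraction
#> 1          1    0.51    1.21            0.70         1.1       0.6363636
#> 2          2    1.61    2.30            0.69         1.1       0.6272727
#> 3          3    2.71    3.41            0.70         1.1       0.6363636
#> 4          4    3.81    4.50            0.69         1.1       0.6272727
#> 5          5    4.91    5.61            0.70          NA              NA

validate_recordings(sig, trial$reference, cfg$body_mass)
#> Insole vs reference validation
#>   strides: insole 5, reference 5, paired 5
#>   MAE  HS 0.000 s (0.00%)  TO 0.050 s (7.69%)  stance 0.050 s (7.69%)
#>   rho_vGRF 0.951  rho_CoP 0.997  RMSE_CoP 0.62 cm
#>   repeatability: vGRF 1.82% (insole) 0.00% (ref); CoP 0.10 cm (insole) 0.00 cm (ref)
#>   vGRF peak: 21.6 BM% (insole) vs 109.9 BM% (ref)
```

Reading the output: the insole detects heel-strikes on time but holds
toe-off ~50 ms late — the configured 20 ms sensor lag keeps voltages below
the release threshold longer, mimicking silicone viscoelasticity. The CoP
trajectory agrees with the reference almost perfectly (rho 0.997, RMSE
0.62 cm) while the insole's vGRF amplitude is ~20% of the reference's
(22 vs 110 % body mass), reflecting the partial plantar coverage of a
16-sensor insole. Without lag (`lag_tau = 0`) all MAEs drop to zero.

A command-line wrapper covering `simulate`, `process`, `events`,
`validate`, `rank-sensors` and `eval-subset` ships in
`inst/cli/insole-gait` (see `?insole_gait_cli`).

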