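# exomyo

Simulation and analysis of treadmill walking with ankle exoskeletons under
**proportional myoelectric control**.

Portable ankle exoskeletons can be driven directly by the user's own
muscle activity: the soleus surface EMG is band-filtered, rectified and
smoothed into an envelope, scaled by a subject-specific gain into a motor
current (capped at 7.6 A q-axis), and transmitted into a plantarflexion
torque. The scientific questions around such devices concern
neuromechanical *adaptation* — does triceps surae EMG fall with practice,
what fraction of the total ankle moment, power and positive work does the
device contribute, and how far does the device's own angle encoder
disagree with motion capture?

`exomyo` provides both halves of such a study as one tested pipeline:

* **Synthetic study generator** (`gen_config()`, `generate_subject()`,
  `generate_dataset()`): multi-subject recordings of raw multi-channel EMG
  (soleus, medial/lateral gastrocnemius, tibialis anterior, 1000 Hz),
  sagittal joint angles and moments, vertical GRF and exoskeleton-encoder
  angle (100 Hz), walking a 50-minute protocol — 5 min boots only, 5 min
  unpowered, 30 min powered, 10 min deadaptation — with known per-muscle
  adaptation ground truth (soleus −12%, medial gastrocnemius −5%, lateral
  gastrocnemius −17%, tibialis anterior +9% at steady state).
* **Controller** (`preprocess_emg()`, `calibrate()`, `command_current()`,
  `current_to_torque()`, `run_controller()`): the causal chain
  `HP 50 Hz → |·| → LP 8 Hz` (2nd-order Butterworth), gain calibration to
  the current cap, 5% deadband, saturation, and current-to-torque
  transmission (constant or tabulated versus angle).
* **Biomechanics** (`detect_events()`, `select_window()`,
  `time_normalize()`, `joint_power()`, `work_decomposition()`,
  `decompose_ankle()`, `rom_comparison()`): GRF-threshold stride events,
  101-point gait-cycle curves, power/work, and the
  exoskeleton/biological/total ankle decomposition with contribution
  shares.
* **EMG metrics** (`normalize_emg()`, `phase_rms()`, `percent_change()`,
  `smd()`): boots-only normalization, stance/swing RMS, percent change and
  standardized mean difference.
* **Statistics** (`oneway_anova()`, `tukey_hsd()`,
  `spm_anova_permutation()`, `paired_t_sample_size()`): repeated-measures
  ANOVA with Tukey HSD, permutation-based one-dimensional statistical
  parametric mapping (max-F threshold, cluster-mass p-values), and exact
  noncentral-t paired sample-size calculation.
* **Pipeline and IO** (`run_pipeline()`, `analyze_subject()`,
  `write_trial_csv()`, `read_trial_csv()`, `write_report()`): the
  simulate → control → analyze → test chain, deterministic under a fixed
  seed, with CSV/JSON interchange.

## Worked example

Run the full default study — 12 synthetic subjects walking the 50-minute
protocol — and its analysis:

```r
library(exomyo)
report <- run_pipeline(gen_config(seed = 1))
print(report)
#> Proportional myoelectric exoskeleton adaptation report
#>   12 subjects, 30-stride windows, seed 1
#>   EMG percent change, BootsOnly -> PoweredEnd (group mean):
#>     SOL  -11.6%  (ANOVA p = 0.000, SMD = 6.12 non-small)
#>     MG    -5.1%  (ANOVA p = 0.000, SMD = 2.85 non-small)
#>     LG   -16.2%  (ANOVA p = 0.000, SMD = 9.14 non-small)
#>     TA    +8.3%  (ANOVA p = 0.000, SMD = 3.08 non-small)
#>   exoskeleton shares (PoweredEnd): power 0.31, moment 0.18, +work 0.29
#>   exoskeleton peak power: 0.57 W/kg
```

Reading the output: after 30 minutes of powered practice the group's
stance-phase soleus RMS is 11.6% below the boots-only baseline — the
pipeline recovers the generator's configured −12% steady state (the
exponential adaptation has realized 99.3% of it by the end of the
session), and likewise for the other muscles. In the final powered window
the device supplies 18% of the peak total ankle moment, 31% of the peak
total ankle power and 29% of the positive work, with an exoskeleton peak
power of 0.57 W/kg. Unlike the human studies this generator emulates,
the effects are strongly significant, because the synthetic
between-subject variability is deliberately small (see the methods
vignette).

Per-subject pieces are available too, e.g. the controller calibration and
ankle decomposition of subject 1:

```r
report$subject_summaries[[1]]$calibration
#> <calibration_result> gain 21.2 A/mV, threshold 0.018 mV (max env 0.359 mV)
report$subject_summaries[[1]]$decomposition
#> <ankle_decomposition>
#>   peak moment: total 0.79, exo 0.14 Nm/kg (share 18%)
#>   peak power:  total 1.97, exo 0.58 W/kg (share 29%)
#>   positive work: total 0.207, exo 0.057 J/kg (share 28%)
```

The encoder-versus-motion-capture range-of-motion comparison works
directly from per-condition dorsiflexion/plantarflexion endpoints (deg):

```r
rom_comparison(bio = data.frame(df = c(5, 8, 8), pf = c(20, 14, 14)),
               exo = data.frame(df = c(7, 2.5, 2.5), pf = c(4, 6, 7)))
#> $per_condition
#>   rom_bio rom_exo diff
#> 1      25    11.0 14.0
#> 2      22     8.5 13.5
#> 3      22     9.5 12.5
#>
#> $average
#> [1] 13.33333
```

## Documentation

The methods vignette (`vignettes/exomyo-methods.Rmd`) describes the
controller model and its assumptions, what the generator does and does not
emulate, the analysis conventions (cycle grid, velocity differencing,
share definitions, normalization), the permutation-SPM design, numerical
tolerances, and known limitations.
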