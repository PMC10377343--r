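# ppghr

Heart-rate reconstruction from motion-corrupted wrist PPG.

Wrist-worn PPG sensors lose the cardiac signal whenever the wearer moves
the arm, wrist or fingers. Mechanical artifacts (sensor–skin displacement)
show up in the wrist IMU, but *vascular* artifacts from finger movement —
page turns, writing, tapping — do not, so accelerometer-based artifact
cancellation cannot remove them. `ppghr` implements a routing architecture
for this problem, aimed at soft-attached monitoring wristbands (e.g. for
wearers who do not tolerate tight fixation):

1. every 6-s window of wristband data (PPG @ 20 Hz, accel/gyro @ 10 Hz,
   skin temperature @ 0.1 Hz) is summarised by a 63-feature statistical
   battery and z-normalised (`z = (x - x̄)/σ`, statistics from the training
   split);
2. an AdaBoost decision-tree ensemble (9 NCA-selected features) classifies
   the window's movement group: 1 = rest, 2 = finger movement, 3 = walking;
3. the window is routed by predicted class:
   * class 1 → HR = 60·argmax of the band-passed PPG magnitude spectrum in
     0.6–3 Hz (zero-padded FFT),
   * class 2 → Gaussian-process regressor **B1** (isotropic exponential
     kernel, constant mean),
   * class 3 → bagged regression trees **B2**,
   with both regressors trained on 15 RReliefF-selected features dominated
   by skin temperature, against ECG-derived instantaneous HR labels
   (`HR(i) = 60 / IBI(i)` from Pan–Tompkins R-peaks, devices aligned by
   accelerometer cross-correlation).

Because the study data behind this design were never released, the package
ships a first-class synthetic session generator built on the Beer–Lambert
reflected-intensity model `Io = Ii·exp(−Σ εj·cj(t)·dj(t))`, with mechanical
artifacts coupled to simulated wrist acceleration, finger-burst artifacts
invisible to the IMU, a lagged HR-coupled temperature channel, and a
reference ECG/accelerometer pair with a device clock offset. See
`vignettes/ppghr-methods.Rmd` for the model, all defaults and their
rationale, and known limitations.

## Worked example

Train on eight simulated users, reconstruct two held-out users:

```r
library(ppghr)

cfg      <- pipeline_config(seed = 1)
sessions <- simulate_cohort(10, seed = 1)
wins     <- lapply(sessions, function(s) window_session(process_session(s, cfg), cfg))
train    <- featurize(wins[1:8], cfg)

bundle   <- train_bundle(train, cfg)
result   <- do.call(rbind, lapply(9:10, function(u)
              reconstruct(sessions[[u]], bundle, cfg, windows = wins[[u]])))
evaluate_reconstruction(result)
```

Output (about 6 minutes on one CPU):

```
accuracy: 98.8%
  class precision recall    f1
1     1     0.985  0.989 0.987
2     2     0.979  0.968 0.973
3     3     0.998  1.000 0.999
RMSE total: 8.47 bpm (FFT-only baseline: 14.09 bpm)
RMSE per task: 1: 2.74, 2: 9.55, 3: 11.96
```

Reading: the activity classifier transfers to unseen users at ~99%
accuracy; routing beats the no-algorithm baseline (every window through the
FFT path) by ~6 bpm overall, with the largest gain on walking windows
(12.0 vs 22.4 bpm) where the gait oscillation hijacks the PPG spectrum.
Rest windows are already accurate through the FFT path, and regression from
temperature-dominated features caps the error during movement.

## Command line

```sh
Rscript -e 'ppghr::ppghr_cli()' simulate --users 2 --seed 1 --out sessions
Rscript -e 'ppghr::ppghr_cli()' featurize --in sessions/user01 --out windows.csv --seed 1
Rscript -e 'ppghr::ppghr_cli()' train --in windows.csv --out bundle --seed 1
Rscript -e 'ppghr::ppghr_cli()' reconstruct --session sessions/user02 --bundle bundle --out rec.csv
Rscript -e 'ppghr::ppghr_cli()' evaluate --result rec.csv --out report.json
```

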