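# wingbeat

Wingbeat-resolved kinematic and neural population analysis for free
flight.

`wingbeat` is an R package for laboratories recording motor cortical
populations in freely flying animals (bats being the motivating case)
alongside 3D pose tracking and body-mounted accelerometers. Flight
unfolds on two nested timescales — a fast, quasi-periodic wingbeat cycle
near 8 Hz (~125 ms) and slow, multi-second flight paths flown at ~4–5
m/s — and the package provides the full analysis chain from raw
synchronized streams to population-level statistics:

* **Flight kinematics** — flight segmentation, agglomerative path
  clustering on trajectory RMS distance (direction-sensitive), derived
  kinematics (speed, g-force `|a|/g`, angular velocity `|v×a|/|v|²`,
  flight-path angle `asin(v_z/|v|)`), leave-one-out flight-to-flight
  reproducibility, and re-projection of pose keypoints into the body
  frame.
* **Wingbeat analysis** — cycle detection from the band-passed
  dorsoventral accelerometer via the analytic-signal phase, per-cycle
  stroke envelopes and left–right asymmetries, per-cycle "adaptation
  vectors" with cosine-similarity lag curves, and kinematic grouping of
  wingbeats across flights of a path.
* **Unit statistics** — circular-shift permutation tests for flight
  modulation (Benjamini–Hochberg FDR, q = 0.01), silent-wingbeat
  fractions, spike-phase resultant vector length
  `R = |Σ e^{iθ_k}|/n` with per-flight rotation nulls (BH per path,
  q = 0.05), sliding wingbeat-window rasters, and cross-path wingbeat
  phase decoding by regression on `[sin θ, cos θ]` with a normalized
  R² score.
* **Recruitment decoding** — binary wingbeat "barcodes" (unit active vs
  silent per cycle), one-vs-rest linear SVM decoding of wingbeat group
  with stratified cross-validation, band accuracies and label-shuffle
  nulls, population-vector similarity lag curves, and cross-path
  divergence traces with within-path controls.
* **Encoding models** — per-unit Poisson GLMs of per-cycle spike counts
  on 17 z-scored kinematic features, elastic-net feature selection
  (5-fold CV, one-SE rule), deviance-based cross-validated pseudo-R²,
  and the normalized participation ratio `(Σw²)²/Σw⁴` of model weights.
* **Population dimensionality** — group-mean population matrices with
  split-half reliability filtering, PCA spectra with `n90` and
  core/extended participation ratios, demixed PCA splitting variance
  into wingbeat-group–specific vs group-invariant components, and GPFA
  (EM with per-factor squared-exponential GP timescales) with
  leave-one-neuron-out dimensionality selection under a 1% rule.
* **Synthetic sessions** — `simulate_session()` generates complete
  sessions (trajectory, 20 keypoints, accelerometer, spikes from four
  planted unit classes, optional shared latent factors) from a single
  seed, with every planted parameter returned as ground truth. All
  validation is property-based against this generator.

## Worked example

Simulate a session with two flight paths (the same ellipse flown in
opposite directions) and a mixed unit population, then run the core
stages:

```r
library(wingbeat)

cfg <- generator_config(seed = 1, n_paths = 2, flights_per_path = 6)
session <- simulate_session(cfg)
session
#> <wb_session> 63.8 s @ 120 Hz, 12 flights, 24 units, 297 wingbeats

fs <- session$meta$sample_rate_hz
flights <- segment_flights(session$trajectory, fs)
flights$path <- as.integer(cluster_paths(session$trajectory, flights))
table(flights$path)
#> 1 2
#> 6 6

det <- detect_wingbeats(session$accel$az, fs, flights,
                        t = session$accel$t)
period_statistics(det)
#> $median_ms [1] 125.027
#> $iqr_ms    [1] 3.126798
#> $n         [1] 300
```

Twelve flights are segmented and clustered into the two planted paths;
300 wingbeat cycles are detected with the planted ~125 ms period and
small jitter. Unit 1 is a planted phase-locked unit; its spike phases
concentrate strongly on the wingbeat cycle:

```r
ph <- phase_at(det, session$spikes$t[session$spikes$unit_id == 1])
ok <- !is.na(ph$phase)
set.seed(1)
r <- phase_locking_test(ph$phase[ok], ph$flight_id[ok], n_shuffles = 500)
unlist(r)
#>          rvl   pref_phase            p            n
#> 8.567197e-01 2.432181e+00 1.996008e-03 2.530000e+02
```

The resultant vector length (0.86) is far outside the rotation null
(p = 1/501, the permutation floor). Finally, decode which wingbeat of
the path each cycle is, from the binary population barcode alone:

```r
wbt <- det$wingbeats
w1 <- wbt[wbt$flight_id %in% flights$flight_id[flights$path == 1], ]
w1$group <- w1$ordinal
B <- build_barcodes(session$spikes, w1,
                    units = sort(unique(session$spikes$unit_id)))
set.seed(1)
dec <- decode_wingbeat_group(B, w1$group)
c(accuracy = dec$accuracy, band1 = band_accuracy(dec$confusion, 1))
#>  accuracy     band1
#> 0.2000000 0.5066667
```

With only 24 units the exact wingbeat is identified far above chance
(1/25 = 0.04), and over half of all predictions fall within one
wingbeat of the truth — recruitment changes smoothly from cycle to
cycle, so decoding errors concentrate next to the diagonal.

`run_pipeline(pipeline_config(seed = 1), "out/")` runs every stage in
dependency order and writes `flights.csv`, `wingbeats.csv`,
`unit_stats.csv`, `phase_pairs.csv`, `decode_report.json`,
`glm_fits.csv`, `dim_report.json` and a provenance `manifest.json`;
reports are byte-identical across runs with the same seed.

## Package layout

```
R/simulate.R        synthetic session generator + ground truth
R/session-io.R      session directory reader/writer (CSV + JSON)
R/flights.R         segmentation, path clustering, kinematics
R/wingbeats.R       cycle detection, envelopes, grouping
R/unit-stats.R      modulation, sparsity, phase locking, phase decoding
R/barcodes.R        barcodes, SVM group decoding, divergence
R/encoding.R        Poisson GLMs with elastic-net selection
R/dimensionality.R  group-mean matrices, PCA, participation ratios
R/dpca.R            demixed PCA
R/gpfa.R            GPFA with LONO dimensionality selection
R/pipeline.R        end-to-end orchestration and reports
```

The methods vignette (`vignettes/wingbeat-methods.Rmd`) documents the
models, their assumptions, all default parameters and the reasoning
behind them, and known limitations.
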