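# sfauc

Analytic quantification of sympathetic arousal from spontaneous skin
conductance fluctuations.

## The problem

Tonic autonomic arousal is classically scored by counting spontaneous
fluctuations (SF) in skin conductance and measuring their amplitudes —
a procedure that needs peak detection, exclusion heuristics and often
visual inspection. Under a linear time-invariant (LTI) model of
electrodermal activity, none of that is necessary. If sudomotor bursts
are impulses \(SN(t) = \sum_i a_i\,\delta(t - T_i)\) driving a
stereotyped response function \(RF\),

\[ SC(t) = SCL + SN(t) \otimes RF(t), \]

then integrating the epoch and subtracting the skin conductance level
(SCL, the epoch minimum) gives

\[ AUC = \int SC(t)\,dt - SCL = c\,n\,\bar a + e,
   \qquad c = \int RF(t)\,dt, \]

so the level-corrected area under the curve carries the same arousal
information as the conventional pair (count \(n\), mean amplitude
\(\bar a\)) — computed in one line, with no subjective element.

`sfauc` is for psychophysiologists and methods researchers who want
to use this measure, or to scrutinise it. It implements:

* the forward convolution model and its containers (`sc_record`,
  `event_train`, `response_function`, `convolve_events`,
  `rf_integral`);
* the AUC statistic (`compute_auc`, `auc_batch`);
* deterministic SF detection by trough-to-peak scoring with the
  conventional 0.025 µS threshold (`detect_sf`, `summarize_sf`);
* least-squares FIR deconvolution of overlapping responses — 120
  stick functions over a (−4, 8) s peak-anchored window at 10 Hz —
  for kernel estimation, per-event amplitudes and variance explained
  (`build_fir_design`, `estimate_rf`, `estimate_amplitudes`);
* the spectral formulation: convolution theorem checks, rectangular
  burst-train Fourier coefficients, and the naive inverse filter whose
  noise fragility motivates the time-domain measure
  (`power_spectrum`, `rect_train_fourier`, `naive_deconvolve`);
* a seeded study simulator with ground truth (`sim_config`,
  `simulate_study`);
* the validation battery: AUC-on-\(n\bar a\) regression, 2×2
  within-subject ANOVA, point-biserial classification and the ΔR² F
  test (`run_validation`, `rm_anova_2x2`, …);
* delimited-text I/O and a CLI pipeline (`read_sc`, `write_study`,
  `sfauc_cli`; script at `inst/exec/sfauc`).

## Worked example

Simulate a small arousal study, score one epoch both ways, then run
the whole validation battery:

```r
library(sfauc)

cfg <- sim_config(n_subjects = 8, seed = 2026)
st  <- simulate_study(cfg)

ep <- st$epochs[[3]]          # subject S01, epoch R1 (anticipation)
compute_auc(ep$record)
#> <auc_result> AUC = 22.72 uS.s over 60 s (SCL = 1.862 uS)

ev <- detect_sf(ep$record)    # conventional arm
summarize_sf(ev)[c("n", "abar")]
#> $n: 9      $abar: 0.407
```

The epoch's AUC (22.72 µS·s) is the integral above the epoch minimum;
the conventional score says 9 fluctuations of mean amplitude 0.41 µS.
Multiplying \(n\bar a = 3.66\) µS by the generating kernel's integral
\(c = 4.30\) s predicts 15.7 µS·s — the shortfall is the trough-to-peak
bias of conventional scoring under overlap, which is exactly the kind
of discrepancy the validation battery quantifies:

```r
run_validation(st)
#> <validation_report>
#>   slope = 5.373 s (c = 4.525 s), intercept = 2.784 uS.s, r2 = 0.986
#>   FIR variance explained = 58.8%, amplitude model = 95.4%
#>   treatment F: auc 40.80, conventional 39.00; interaction 13.52
#>   classification r: auc 0.695 vs conventional 0.703 (dR2 F = 0.62, p = 0.436)
```

Reading the report: AUC and \(n\bar a\) share 98.6% of their variance
across the 32 epochs; the regression slope (5.37 s) sits above the
FIR-estimated kernel integral (4.53 s) because detection under-scores
overlapping fluctuations; the per-peak amplitude model explains 95% of
the signal variance (time-invariance holds in this simulation by
construction); and both measures detect the anticipation treatment
(F(1,7) ≈ 40) with a strong positive classification correlation.

The same pipeline runs from a shell:

```sh
sfauc simulate --config cfg.yaml --out study/ --seed 7
sfauc detect   --in study/S01_R1.csv --threshold 0.025 --out ev.csv
sfauc auc      --in study/S01_R1.csv --out auc.json
sfauc fir      --data study/ --window -4 8 --out rf.csv
sfauc validate --data study/ --out report.json
```

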