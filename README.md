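# lfpvc — volume conduction and the LFP recording montage

Local field potentials are most often recorded *referentially* (RR): one
electrode in the structure of interest against a distant reference screw.
Because brain tissue conducts, such a channel picks up every current source
between electrode and reference — volume conduction — and coherence or
cross-correlation between two referential channels can reflect a shared
distant source rather than genuine inter-areal communication. A
*differential* (bipolar, DR) montage subtracts two contacts a distance
2ε apart in the same structure and cancels the common part of distal
sources.

`lfpvc` is an R package for quantifying that difference. It provides:

* the closed-form ohmic point-source forward model: potentials, exact /
  distal / local electrode-pair differences, the common-mode rejection
  ratio **Γ = (√2/4)(r/ε)²**, and the montage signal-to-noise ratios
  SNR_RR = r/ε, SNR_DR = Γ, their ratio γ = (√2/4)(r/ε) (unity at
  r = 2√2 ε ≈ 3ε) and the rounded-per-axis 3-D advantage γ³;
* a hypnogram-driven synthetic generator for two-area (CA1, PFC) sleep
  sessions rendered through the forward model, with known ground truth:
  REM theta, NREM slow oscillation and spindles, sporadic 10–14 Hz bursts
  common to both areas with a fixed 35 ms inter-areal delay, per-area pink
  background, a strong distal common source, a state-gated EMG channel,
  and EDF + CSV/JSON session files;
* the analysis pipeline: state-conditioned Welch spectra, spectrograms,
  magnitude-squared and imaginary coherence, burst detection
  (band-pass → Hilbert envelope → mean + 2 SD threshold), burst-triggered
  coherence, per-event cross-correlation peak-lag distributions, automatic
  sleep scoring, and the coherence-versus-noise simulation with its
  hyperbolic-secant fit;
* an end-to-end `run_all()` workflow producing a deterministic JSON report
  from a single config + seed.

For whom: electrophysiologists weighing montage choices for functional
connectivity, and methods developers who need a ground-truth testbed for
coherence/lag estimators under volume conduction.

## Worked example

```r
library(lfpvc)

theory_table(c(2*sqrt(2), 6, 10, 100))
#>  r_over_eps     cmrr  snr_rr   snr_dr snr_gain snr_global
#>       2.828    2.828   2.828    2.828    1.000          1
#>       6.000   12.728   6.000   12.728    2.121          8
#>      10.000   35.355  10.000   35.355    3.536         64
#>     100.000 3535.534 100.000 3535.534   35.355      42875
```

A pair 10ε from a source rejects it ~35× better than a referential
channel would; at r = 6ε the per-axis DR/RR gain rounds to 2, i.e. an
8-fold three-dimensional advantage.

```r
sess <- simulate_session(seed = 42, n_wake = 6, n_nrem = 20, n_rem = 14)
rem  <- epochize(sess, "REM")
ev   <- detect_bursts(channel_trace(sess, "CA1_DR"), sess$fs, epochs = rem)

lag_distribution(sess, ev, "DR")
#> <lag_distribution> DR mode, 15 events: median 35.0 ms (SD 27.8 ms)
lag_distribution(sess, ev, "RR")
#> <lag_distribution> RR mode, 15 events: median 6.0 ms (SD 72.3 ms)
```

The generator injected a 35 ms CA1→PFC burst delay. The differential
montage recovers it exactly as the median per-event cross-correlation
peak lag; the referential montage — dominated by the zero-lag common
source — collapses toward zero with a much broader distribution.

```r
ps_rr <- state_spectrum(sess, "REM", "RR", "CA1")
ps_dr <- state_spectrum(sess, "REM", "DR", "CA1")
band_power(ps_rr, c(0.5, 100)) / band_power(ps_dr, c(0.5, 100))
#> [1] 9.2   # referential power ~10x differential power

cv <- coherence_vs_noise(c(1, 2, 5, 10, 15, 20, 30), seed = 42)
cv$coherence[cv$noise_sd == 10]   # 0.511: per-bin SNR = 1 -> C ~ 0.5
fit_sech(cv)$a                    # 0.122: sech scale of the decay
```

The whole pipeline (simulate → score → spectra → coherence → bursts →
lags → noise curve → theory table) runs as one reproducible unit:

```r
report <- run_all(pipeline_config(seed = 1))
report_json(report)   # byte-identical for identical config + seed
```

The methods vignette (`vignettes/lfp-montage-methods.Rmd`) documents the
model, the generator's calibration and every estimator decision.

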