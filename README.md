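# hippodesync

Analysis pipeline linking **hippocampal neural desynchrony to
hyperlocomotion** in the early-postnatal MK-801 (NMDA-receptor antagonist)
mouse model of schizophrenia, with an aripiprazole (ARI) treatment arm.

The package is written for electrophysiologists and imaging labs who need
the full measurement chain behind this phenotype:

* **LFP**: zero-phase band-splitting (LFP 1–300 Hz, spikes 300–5000 Hz),
  multitaper power spectra, integrated band power in delta (1–4 Hz),
  theta (5–12 Hz), beta (13–30 Hz) and gamma (30–80 Hz).
* **Spikes**: regular-spiking / fast-spiking classification (width-primary,
  0.45 ms trough-to-peak boundary), instantaneous firing rates, and
  spike-count-equalized **spike–field coherence**: for N randomly selected
  spikes during locomotion, the 300 ms of LFP around each spike is averaged,
  and at each frequency

  `SFC(f) = 100 × PSD[spike-triggered average](f) / mean_i PSD[window_i](f)`

  giving 0–100%: 100% for perfect phase-locking, ≈100/N for spikes
  independent of the field. Theta-band SFC is the maximum over 5–12 Hz; the
  population summary counts units whose peak exceeds 20%.
* **Calcium imaging** (10 Hz traces): transient detection on raw traces
  (height 20, distance 10 frames, prominence 20), decay-constant estimation
  on the 10 best-isolated transients with a 2.5 s failed-extraction rule,
  per-neuron rates and amplitudes.
* **Correlations**: Fisher-corrected (z = atanh r) Pearson/Spearman pairwise
  correlations of z-scored traces and neuron–speed correlations, with
  cumulative-distribution summaries.
* **Behavior**: open-field total distance and % time in the 25%-area center
  (55 × 40 cm arena); Student's t and two-way ANOVA with Šídák post-hoc
  contrasts for group × treatment designs.
* **Synthetic sessions**: a generator with `VEHICLE`, `MK801`, `VEHICLE_ARI`
  and `MK801_ARI` presets emulating the conditions — theta-locked von Mises
  spiking, latent-driven calcium dynamics, bout-structured locomotion — so
  the whole pipeline is testable end to end without the (undeposited)
  recordings.

## Worked example

```r
library(hippodesync)

veh <- generate_session("VEHICLE", seed = 1, duration_s = 120)
mk  <- generate_session("MK801",   seed = 1, duration_s = 120)

rbind(session_metrics(veh), session_metrics(mk))[,
  c("group", "theta_power", "gamma_power", "theta_sfc_all",
    "transient_rate_per_min", "pairwise_corr_z")]
#>     group theta_power gamma_power theta_sfc_all transient_rate_per_min pairwise_corr_z
#> 1 vehicle      1280.5      82.831        48.353                 4.8333        0.079961
#> 2   mk801      2841.8     144.772        14.153                 7.3000        0.044066
```

Read: at the same seed (matched condition-independent randomness), the
MK-801 session has ≈2.2× theta and ≈1.7× gamma band power (µV²), its units'
mean theta spike–field coherence drops from ≈48% to ≈14%, calcium transients
are more frequent, and the mean Fisher-z pairwise correlation between
neurons is roughly halved — hyperactivity with desynchrony, the signature
the pipeline measures.

The `analysis/` directory holds the full numbered workflow
(`01_simulate_sessions.R` … `06_behavior_report.R`): simulate a four-arm
cohort, write it to `results/sessions/` in the plain-text session format,
then run each analysis stage and write its tables under `results/`.

```sh
for f in analysis/0*.R; do Rscript "$f"; done
```

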