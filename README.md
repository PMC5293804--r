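# reachgrasp

Simulation and analysis of reach-to-grasp kinematics for
language-and-motor-control experiments.

## What this is for

In sentence-fragment paradigms, participants read a subject pronoun
(*I*, *YOU*, *HE*) followed by an action verb (e.g. *to grasp*) or an
interaction verb (e.g. *to give*), and reach for and grasp an object as
soon as the verb is identifiable, while three motion-capture markers
(wrist, index, thumb) track the hand. The scientific question is
whether the linguistically induced perspective modulates movement
planning; the diagnostic parameter is the latency of the wrist velocity
peak normalized by reach time, `%t_vpeak = 100 * t_vpeak / reach_time`,
because a relatively earlier peak (longer deceleration) marks the
planning of a subsequent motor act.

`reachgrasp` implements the full analysis chain for such experiments,
plus a calibrated synthetic-data generator so every stage is testable
without access to raw recordings:

* **Generator** — beta-family speed profiles `v(tau) ∝ tau^a (1-tau)^b`
  (minimum-jerk at peak fraction 0.5, peak speed `1.875 D/T`) with
  controllable peak latency, concurrent grip-aperture profiles, subject
  and trial variability, catch trials, anticipations, linguistic
  errors, and measurement noise; calibrated so that the segmentation
  rules recover the configured condition means. Presets mirror a 60 Hz
  optical design (12 subjects, 40-trial blocks, 330 mm reach) and a
  200 Hz electromagnetic design (13 subjects, 100-trial blocks,
  350 mm).
* **Kinematics** — zero-phase Butterworth filtering, tangential speed,
  two published movement-segmentation rules (per-axis 0.3 mm
  displacement thresholds with a grasp-end tie-break; 1 mm/s velocity
  threshold), and extraction of reach time, velocity-peak amplitude and
  latency, normalized latency, grasp time, maximal finger aperture and
  its latency.
* **QC** — trial rejection (errors, anticipations, segmentation
  failures, catch trials) and exclusion of participants with less than
  50% valid trials.
* **Inference** — per-subject condition means; 2 x 3 repeated-measures
  ANOVA with partial eta squared (`eta_p^2 = F df1 / (F df1 + df2)`);
  planned one-sided paired comparisons with Bonferroni-type correction;
  and a JZS (default-prior) Bayes-factor ANOVA for the full model
  against the subject-only null, integrated by seeded Monte Carlo.

File formats are plain text: a long CSV for trajectories (one row per
trial x marker x frame), TSVs for per-trial parameters and all result
tables, YAML for run configuration, JSON for the run manifest.

## Worked example

Simulate the 60 Hz design with realistic noise and run the complete
pipeline:

```r
library(reachgrasp)
cfg <- run_config(generator = generator_preset("exp1_italian"), seed = 42,
                  parameters = c("reach_time_ms", "pct_t_vpeak"))
res <- run_pipeline(cfg, "demo_run", write_trajectories = FALSE)
res$report
```

The condition-mean table recovers the preset calibration (reach times
in ms, normalized latencies in %), and the inference tables show, for
this seed:

```
Repeated-measures ANOVA:
         effect      F df1 df2      MSE         p eta_p2     parameter
           Verb  1.539   1  11 240.8109 2.406e-01 0.1227 reach_time_ms
        Pronoun 35.291   2  22 118.5282 1.364e-07 0.7624 reach_time_ms
 Verb x Pronoun 66.603   2  22 174.4730 4.642e-10 0.8583 reach_time_ms
           Verb  9.160   1  11   1.5424 1.152e-02 0.4544   pct_t_vpeak
        Pronoun 33.643   2  22   0.5250 2.032e-07 0.7536   pct_t_vpeak
 Verb x Pronoun 91.711   2  22   0.9581 2.126e-11 0.8929   pct_t_vpeak

Planned comparisons (pct_t_vpeak rows):
      comparison        t df         p mean_diff sided direction
     I.AV - I.IV -6.12549 11 3.731e-05  -2.44483   one      less
 YOU.AV - YOU.IV 12.13342 11 5.191e-08   5.06615   one   greater
   HE.AV - HE.IV  0.07415 11 4.711e-01   0.03654   one   greater
```

Read: with 12 simulated subjects the verb-by-pronoun interaction in the
normalized velocity-peak latency is recovered (`F(2,22)`, `eta_p2`
column), and the planned comparisons localize it: action verbs peak
about 5 percentage points later than interaction verbs after *YOU*
(the generator injects a 4.8-point difference there), a reliable
difference at the corrected alpha, while the *HE* cells do not differ.
The simulated effects are more regular across subjects than real
recordings, hence the large F values; the generator calibrates means,
not effect-size heterogeneity.

The same pipeline is scriptable from a shell:

```sh
reachgrasp simulate --config cfg.yaml --seed 7 -o out/
reachgrasp extract --variant exp1 out/trajectories.csv -o out/
reachgrasp analyze out/trial_params.tsv --preset fixed-alpha -o out/
reachgrasp run --config cfg.yaml --seed 7 -o out/   # all stages
```

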