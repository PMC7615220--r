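# galpop

Analysis pipeline for quantifying how pregnancy remodels a hypothalamic
parenting population — the galanin-expressing neurons of the medial preoptic
area (MPOA-Gal). Pregnancy hormones silence part of this population while
making the remaining neurons more excitable and more selective for infant
(pup) stimuli; `galpop` implements the statistics that make that pattern
measurable, for anyone analyzing event-aligned calcium imaging,
intracellular recordings, and bout-level behavior across reproductive (or
other) states.

The package covers three layers, each testable end-to-end on a built-in
synthetic-data generator that returns its planted ground truth:

* **Behavior** — bout summaries (retrieval latency with right-censoring,
  crouch/nest-time fractions), Kaplan–Meier survival curves with log-rank
  tests, and behavior-transition matrices `P_T` with per-edge Mann–Whitney U
  comparisons between groups.
* **Intracellular physiology** — spike detection, baseline firing and
  resting potential, silent-cell classification (< 0.05 Hz), depolarization
  block across current steps, action-potential half-width, and spontaneous
  postsynaptic current (sPSC/EPSC/IPSC) detection.
* **Population imaging** — per-neuron Z-scoring, detected (non-silent)
  neuron counts, event-aligned responses with a sign-permutation activation
  test, onset latencies, onset-ordered hierarchical clustering, tuning index
  `TI = (mu_resp − mu_base) / (|mu_resp| + |mu_base|)`, pairwise selectivity
  `S = A_pup / (A_pup + A_other)` (1 = pup-exclusive, 0.5 = non-selective,
  0 = other-exclusive), and stimulus separability: temporal-bin features →
  shrinkage Fisher LDA → k-means partition → Rand Index
  `RI = (a + b) / C(n, 2)`, with 95% confidence ellipsoids per stimulus.

## Worked example

Generate a late-pregnancy-like (D18) session — 60 neurons, 45% planted
silent, pup-tuned transients — and run the population analyses:

```r
library(galpop)

cfg <- state_preset_config("D18", n_neurons = 60, seed = 1)
s   <- generate_population_session(cfg)

res <- evoked_summary(s$traces, s$events, "retrieval", seed = 1)
z   <- zscore_traces(s$traces, baseline_mask(s$traces, s$events))
sel <- selectivity_score(align_events(z, s$events, "pup_sniff"),
                         align_events(z, s$events, "object_sniff"))
sep <- separability(s$traces, s$events, c("pup_sniff", "object_sniff"),
                    seed = 1)
```

which prints (via the calls in `analysis/`):

```
detected neurons: 32 / 60 (planted active: 33)
retrieval-activated fraction: 0.25
median pup-vs-object selectivity: 0.90
<separability_result> stimuli {pup_sniff, object_sniff}: RI = 0.548 (512 samples, lambda = 0.01)
```

Read: the detector recovers the planted non-silent population (32 vs 33);
only a quarter of detected neurons are retrieval-activated (the planted
sparsening); detected neurons are strongly pup-selective (median 0.90,
where 0.5 would be non-selective); and pup bouts are partially separable
from object bouts in LDA space. A virgin-like preset
(`state_preset_config("Vir", ...)`) yields the opposite profile — more
detected neurons, higher activated fraction, selectivity near 0.5, lower
Rand Index.

## Analysis workflow

The `analysis/` scripts run the full synthetic study and write tables under
`results/`:

| script | what it does |
| --- | --- |
| `01_simulate_sessions.R` | defines the study: imaging-session manifest, 20 ethograms, 50 patch-cell configs |
| `02_behavior.R` | assay summaries, KM retrieval latency + log-rank, transition-edge U tests |
| `03_ephys_features.R` | per-cell intracellular features by group |
| `04_evoked_population.R` | detected counts, activated fractions, latencies, clustering |
| `05_tuning_selectivity.R` | tuning indices, baseline–tuning regression, selectivity by state |
| `06_separability.R` | per-session Rand Index and the separability–sparseness regression |

Run them in order from the repository root (`Rscript analysis/01_...` etc.);
each prints its findings and is deterministic.

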