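# meanet

Network-burst detection and functional-connectivity analysis for
multielectrode-array (MEA) spike trains.

Cultured neuronal networks on MEAs (typically 60 electrodes) develop
spontaneous *network bursts* — population events in which many electrodes
fire within tens of milliseconds. Their rate, size, and the directed
propagation structure between electrodes are standard readouts for culture
maturation and for disease models such as amyloidosis, where bursting is
progressively suppressed. `meanet` packages that analysis for
electrophysiologists and methods developers:

* **Burst analysis.** A network burst is detected wherever a 50 ms window
  contains ≥ 4 spikes from ≥ 4 distinct electrodes; overlapping qualifying
  windows merge into one event. Bursts with peak amplitude A ≤ 100 spikes
  per 50 ms are *small*, A > 100 *large*. Per recording (or per minute) the
  package reports the five standard activity parameters: burst rates,
  spikes per burst, duration, amplitude, and the proportion of spikes
  inside bursts.
* **Connectivity.** For every ordered electrode pair (m → n) and cumulative
  delay windows k = 1…50 ms, the ratio
  r_k(m→n) = |{target spikes with a source spike preceding by d ∈ (0, k]}| / N_n
  is computed on spikes inside large-burst spans. Pairs are ranked by
  r_50, the top 5% become directed edges weighted by the half-rise delay,
  and hub count, hub coefficient (mean hub degree), and graph diameter
  summarise the network architecture.
* **Synthetic ground truth.** A seeded generator emulates control,
  amyloid-suppressed, and chronically stimulated cultures (condition factor
  δ scaling burst rate, burst size, and transmission probability) with
  planted hub→target edges, so every pipeline stage is testable without
  external data.
* **Statistics.** Kruskal–Wallis group comparison (tie-corrected, exact
  permutation option for N ≤ 10), ΔΔCt relative expression
  (2^(−ΔΔCt)), and fold changes versus each group's DIV14 baseline.

See `vignettes/mea-network-analysis.Rmd` for the full methods description.

## Worked example

```r
library(meanet)

# a synthetic 10-minute, 60-electrode recording of an intact culture
cfg <- synthetic_config(seed = 42, recording_id = "demo",
                        group_label = "Intact", div = 14L)
s <- generate_recording(cfg)$recording
s
#> spike_train_set: 60 electrodes, 33130 spikes, 600.0 s
#>   id=demo group=Intact DIV=14

bursts <- detect_network_bursts(s)
head(as.data.frame(bursts), 3)
#>     start_s     end_s duration_ms total_spikes n_electrodes peak_rate size_class
#> 1 0.1258846 0.2440021      118.12          311           60       279      large
#> 2 0.9422026 1.0268231       84.62          295           60       273      large
#> 3 2.3282157 2.4283951      100.18          290           60       269      large

st <- compute_burst_statistics(s, bursts)
```

The statistics row says this culture fires 2.8 small and 9.0 large bursts
per minute, large bursts average 309.3 spikes, and 84.36% of all recorded
spikes fall inside network bursts — a typical profile for a mature, healthy
culture, where most activity is burst-locked.

```r
profiles <- pair_sync_profiles(s, bursts, restrict = "large")
graph <- build_connectivity_graph(rank_pairs(profiles))
graph
#> connectivity_graph: 58 nodes, 177 edges (top 5% of 3540 positive pairs)
hub_metrics(graph)[c("n_hubs", "hub_coefficient", "diameter")]
#> $n_hubs
#> [1] 6
#> $hub_coefficient
#> [1] 26
#> $diameter
#> [1] 4
```

The three planted initiator hubs (and their strongest relays) emerge as the
high-degree nodes of the directed graph. `write_connectivity()` exports the
graph as GraphML plus edge/node CSVs.

For longitudinal designs, `generate_longitudinal()` +
`longitudinal_summary()` produce one row per recording with fold-change
columns versus each group's DIV14 mean, `group_comparisons()` adds
Kruskal–Wallis tests per DIV, and `run_analysis(pipeline_config(...))` runs
the whole pipeline into a report directory (deterministic under a fixed
seed). A thin CLI lives at `inst/scripts/run_pipeline.R`.

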