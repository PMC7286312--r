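# ieegjack

Network analyses of intracranial EEG (iEEG) are increasingly used to
localize epileptic tissue and characterize seizure dynamics, but every such
analysis sees only the contacts a surgical team happened to implant.
`ieegjack` asks the question that clinical interpretation depends on: **how
much would a network result change if the electrode sampling had been
slightly different?** It provides the full pipeline — coherence-network
construction, weighted graph metrics, electrode-subsampling schemes,
reliability and agreement statistics, and patient-specific jackknife
confidence sets — for neuroscientists and methodologists working with
multichannel electrophysiology, plus a synthetic-data module so everything
is testable without clinical recordings.

## The methods in brief

**Networks.** Signals are common-average referenced, elliptic-bandpass
filtered (5–115 Hz) with a 60-Hz notch, and AR-prewhitened; edges of an
undirected weighted network are then band-averaged multitaper
magnitude-squared coherences between contact pairs in 1-s windows
(high gamma 95–105 Hz by default, beta 15–25 Hz as an alternative), with
optional thresholding to a target density.

**Graph metrics.** Global: global efficiency
*E* = (1/*N*(*N*−1)) Σ<sub>i≠j</sub> 1/σ<sub>ij</sub> (Dijkstra lengths
1/weight); synchronizability *Sync* = λ₂/λ<sub>max</sub> of the weighted
Laplacian *L* = *D* − *A*; weighted transitivity *T* = Στ<sub>Δ</sub>/Στ.
Nodal: node strength *s*<sub>i</sub> = Σ<sub>j</sub> *A*<sub>ij</sub>,
eigenvector centrality (leading eigenvector of *A*), weighted betweenness,
control centrality
*c*<sub>i</sub> = (*Sync*<sub>new</sub> − *Sync*<sub>old</sub>)/*Sync*<sub>old</sub>
under virtual removal of contact *i*, weighted clustering, and regional
control centrality for contiguous regions of a chosen size (a virtual
resection).

**Robustness.** Contacts are removed at random (20–80%, 1000 iterations),
in contiguous patches, or by targeting/sparing the clinician-marked seizure
onset zone; metrics are recomputed on each subnetwork. Reliability
*R* = σ²<sub>T</sub>/(σ²<sub>T</sub> + σ²<sub>E</sub>) partitions metric
variance into true-score and subsampling components; agreement *a* is a
Spearman correlation (nodal) or negative absolute relative difference
(global); Friedman + Dunn–Šidák tests compare metrics across a cohort.
Jackknife subsampling (random 20% removal, 1000 iterations) yields the 95%
confidence contact set for nodal localizations and the 95% confidence
interval for global metric values — a patient-specific error bar on "which
contact is the hub" and "how synchronizable is this network".

## Worked example

```r
library(ieegjack)

lay <- simulate_layout(6, 8, 10, n_soz = 6, seed = 1)   # 48-contact grid
sim <- simulate_recording(lay, duration = 2, n_groups = 4, seed = 1)
rec <- preprocess(sim$recording)                         # CAR + filter + AR(1)
net <- multitaper_coherence_network(rec, window_start = 0.5, window_len = 1)
net
#> <functional_network> 48 contacts, density 1.000
#>   band: high_gamma [95, 105] Hz
#>   window: start 0.5 s, length 1 s

round(global_metrics(net), 3)
#> global_efficiency synchronizability      transitivity
#>             0.680             0.429             0.623

ens  <- random_subsample(net, fraction = 0.2, n_iter = 1000, seed = 1)
vals <- ensemble_metric(ens, net, "node_strength")
reliability_nodal(vals, "node_strength", 0.2)
#> <reliability_report> node_strength: R = 0.9714 (var_true 16.65, var_error 0.4901, 1000 iterations)

jackknife_nodal_confidence_set(net, "node_strength", fraction = 0.2,
                               n_iter = 1000, seed = 1)
#> <confidence_set> node_strength (max): 3 contacts covering 97.0% of 1000 iterations

jackknife_global_interval(net, "synchronizability", fraction = 0.2,
                          n_iter = 1000, seed = 1)
#> <confidence_interval> synchronizability: [0.3999, 0.4583] (width 0.0584, point 0.4295, 1000 iterations)
```

Reading the numbers: node strength on this four-block network is highly
reliable under 20% random contact removal (*R* = 0.97 — only ~3% of its
variance is subsampling noise), the identity of the strongest contact is
pinned down to 3 candidate contacts at 95% confidence, and the network's
synchronizability carries an uncertainty band of about ±0.03 due to
electrode sampling alone.

A command-line interface wrapping the same functions is installed at
`inst/cli/ieegjack` (subcommands `simulate`, `network`, `metrics`,
`subsample`, `reliability`, `jackknife`, `cohort`).

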