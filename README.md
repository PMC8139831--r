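# devconn

Tools for asking how neuronal development shapes circuit structure in
synapse-resolution connectomes. In insect nerve cords every neuron carries a
developmental address: its neuroblast **lineage**, the Notch-defined
**hemilineage** (dorsal vs ventral projection), and its **temporal cohort**
(birth window, proxied by the cortex neurite length from soma to neuropil
entry). `devconn` implements the analysis chain that tests whether the
intersection of the last two — the **hemilineage-temporal (HL-T) cohort** —
is a unit of circuit assembly:

* **Core I/O** — SWC skeletons, polyadic connector tables (one presynaptic
  site, ≥ 1 postsynaptic partners), annotation tables, neuropil volumes,
  synaptic count matrices and binarization.
* **Morphometrics** — Strahler ordering and pruning, neuropil entry and
  cortex neurite length, temporal-cohort binning from reference marker
  cells, dotprops conversion and kernel-based morphology clustering into
  hemilineages.
* **Synapse maps** — the spatial synapse-similarity kernel
  `f = exp(-d²/2σ²)·exp(-|n_i - n_j|/(n_i + n_j))` with σ = ω = 2000 nm,
  its pre/post overlap variant (a proximity proxy for potential
  connectivity), bilateral averaging over homolog pairs, and weighted 2D
  kernel density maps with mass-referenced contours.
* **Connectivity** — premotor/postsensory classification, group
  input/output fractions, cosine connectivity similarity on binarized
  matrices, undirected synaptic network distance, and cohort comparisons
  (Wilcoxon rank-sum, Kolmogorov–Smirnov).
* **Null models** — degree-preserving Monte-Carlo shuffles with
  input-degree or overlap-based connection probabilities, the HL-T
  connection-frequency statistic, and add-one empirical p-values: does
  cohort-to-cohort connectivity exceed what proximity alone predicts?
* **Synthetic connectomes** — a ground-truth-labelled generator
  (`generate_connectome()`) emulating bilateral hemisegments with radially
  layered somata, dorsal/ventral synapse clouds, polyadic connectors,
  proximity-driven connectivity and a tunable cohort-wiring bonus ε, so
  every stage is testable without an electron-microscopy dataset.

See the methods vignette (`vignettes/devconn-methods.Rmd`) for the models,
their assumptions, and the design decisions.

## Worked example

Generate a small labelled connectome, recover its temporal cohorts, and ask
whether HL-T cohorts wire beyond proximity:

```r
library(devconn)

cfg <- generator_config(n_lineages = 3, temporal_groups_per_hemilineage = 2,
                        hlt_bonus = 4, seed = 1)
cn  <- generate_connectome(cfg)
cn
#> <synthetic_connectome> 120 neurons, 1188 connector rows, 96 designated
#>   cohort pairs, seed 1

# cortex neurite length, averaged over bilateral homologs
ann  <- cn$annotations
lens <- vapply(cn$skeletons, cortex_neurite_length, numeric(1),
               volume = cfg$neuropil)
bins <- fit_temporal_bins(cn$reference_lengths$hb, cn$reference_lengths$cas)
bins
#> <temporal_binning> t1 = 1.444e+04, t2 = 2.682e+04, t3 = 3.618e+04 nm
#>   (n_hb = 80, n_cas = 80)

# proximity null for the HL-T connection frequency
b     <- binarize(build_connectivity(cn$connectors, ann$neuron_id), 1)
O     <- overlap_matrix(list(pre = cn$pre_clouds, post = cn$post_clouds))
model <- connection_probabilities("overlap", overlap_matrix = O)
null_distribution(b, model, hlt_cohort(ann), n_iter = 500, seed = 2)
#> <null_test> cohort connection frequency (pair_both reading)
#>   observed 0.0821 vs overlap null: mean 0.0637, empirical p = 0.001996
#>   (500 shuffles)
```

The observed frequency with which both members of an HL-T cohort contact
the same other cohort (0.082) exceeds the mean of 500 out-degree-preserving
proximity shuffles (0.064); the add-one empirical p of 0.002 says none of
the shuffles reached the observed value — the cohort-wiring bonus baked
into this connectome (ε = 4) is detected. Regenerating with `hlt_bonus = 0`
makes the same p-value uniform on (0, 1].

The full analysis — morphometrics, similarity matrices, density maps,
cohort statistics and nulls — runs as one call:

```r
report <- run_pipeline(pipeline_config(generator = cfg, seed = 1,
                                       output_dir = "results/"))
```

and a thin command-line wrapper is included:

```sh
Rscript inst/scripts/connectome-pipeline.R generate --seed 1 --out fix/
Rscript inst/scripts/connectome-pipeline.R run-all --in fix/ --out results/
```

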