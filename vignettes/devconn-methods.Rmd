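---
title: "Relating developmental origin to circuit structure: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relating developmental origin to circuit structure: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

In insect nerve cords, every neuron is born from an identified neuroblast
(its lineage), inherits one of two Notch states that split the lineage into a
dorsal and a ventral **hemilineage**, and is stamped by the temporal
transcription-factor window in which it was born (its **temporal cohort**,
proxied anatomically by the length of the neurite from the soma to the
neuropil entry point — later-born somata are displaced outward through the
cell-body cortex). The intersection of the two — a **hemilineage-temporal
(HL-T) cohort** — is a candidate unit of circuit assembly: a handful of
neurons with shared birth window and shared Notch state that may wire into
the same microcircuits.

`devconn` implements the computational side of that question for a
synapse-resolution connectome: skeleton morphometrics that recover
developmental labels, spatial statistics of synapse placement, connectivity
statistics, and Monte-Carlo null models that ask whether HL-T cohorts share
synaptic partners *beyond what mere axon–dendrite proximity predicts*.
Because the question is distributional, every stage is validated against a
synthetic connectome generator with known ground truth.

## Morphometrics

**Cortex neurite length.** A skeleton is a rooted tree with the soma as
root. The neuropil entry point is the skeleton node inside the neuropil
volume with minimal geodesic (along-the-cable) distance from the root;
cortex neurite length is that geodesic distance in nm. It is invariant to
node re-indexing and to edge subdivision, and bilateral homologs are
averaged (`bilateral_mean_length()`) to cancel side-specific noise.

**Temporal binning.** Cortex lengths of identified early-marker-positive
(Hb+) and late-marker-positive (Cas+) reference cells define four bins:

* `t1 = mean(hb) + sd(hb)` — group 1 is `L < t1`;
* `t2 = mean(cas) - sd(cas)` — group 2 is `t1 <= L <= t2`;
* `t3 = mean(cas)` — group 3 is `t2 < L <= t3`, group 4 is `L > t3`.

The sample (n−1) standard deviation is used, since the reference sets are
small empirical samples. Boundaries are owned as written above (group 2 owns
both of its endpoints), making the assignment exhaustive, exclusive and
monotone in `L`. If the reference distributions overlap so far that
`t1 > t2`, construction fails rather than silently producing unordered bins.

**Morphology clustering.** Neurons are pruned to Strahler order ≥ 2
(removing the most distal twigs), resampled into dotprops (points every
1000 nm with a local tangent from the five nearest points), and compared
with a Gaussian-times-alignment kernel: each query point contributes
`exp(-d²/(2·sigma_n²))·|u·v|` for its nearest target point, normalized by
the query self-score so self-similarity is exactly 1. This is an analytic
stand-in for empirical log-odds morphology scoring: it is deterministic,
self-contained, and monotone in the same geometric quantities (distance and
tangent alignment). Average-linkage clustering of `1 − (S+Sᵀ)/2` cut at
height 0.65 recovers hemilineages; the cutoff was calibrated on the default
synthetic fixture, where any cut on the wide plateau 0.6–0.75 splits every
lineage into exactly its two hemilineages (adjusted Rand index 1.0). The
pruning level ("to" vs "at" a given order) only affects clustering
robustness, so it is exposed as `keep_min_order` with default 2.

## Synapse-position statistics

The spatial similarity of two synapse sets A and B is the mean over
synapses `s` of A of

```
f(s,k) = exp(-d_sk² / (2σ²)) · exp(-|n_s - n_k| / (n_s + n_k))
```

where `k` is B's synapse nearest to `s`, `d_sk` their Euclidean distance,
and `n_s`, `n_k` the fractions of A's (B's) synapses within `ω` of `s` (`k`).
Defaults are `σ = ω = 2000 nm`. Each synapse counts itself in its own
neighborhood, so the fractions are strictly positive, the second factor is
well-defined, and a set scores exactly 1 against itself. Nearest-neighbor
ties break to the lowest index (measure-zero with continuous coordinates).
The directed score is averaged over the two hemisegments for homolog pairs;
applying it between the presynapses of neuron i and the postsynapses of
neuron j gives the **pre/post overlap**, the proximity proxy used by the
null models. The score is translation- and rotation-invariant, and invariant
under a joint rescaling of coordinates and (σ, ω).

**Density maps.** 2D kernel density estimates of synapse positions on the
transverse (mediolateral × dorsoventral) plane use a Gaussian product
kernel with per-axis Scott's-rule bandwidths by default (the bandwidth is
configurable; no canonical value is fixed by the analysis). Polyadic
weighting counts each presynaptic connector once per postsynaptic partner.
The outermost contour is drawn at the density level whose superlevel set is
the *smallest containing the requested probability mass* (60% for
hemilineage maps, 80% for lineage maps) — a mass-referenced cutoff, not a
fraction of the peak height; the mass reading makes the enclosed region
interpretable as a probability region regardless of peak shape. An
anteroposterior window can restrict the mapped synapses to the segments
where transverse position is comparable.

## Connectivity statistics

Connectivity matrices count (connector, partner) contacts — polyadic
connectors contribute once per partner — and are binarized at a stated
threshold. Connectivity similarity is the cosine similarity of binarized
row vectors (shared outputs) or column vectors (shared inputs); zero
vectors score 0 and are flagged. Network distance is the shortest path
length in the *undirected* support of the binarized matrix: direct partners
are one synapse apart, neurons sharing a common input or output are two —
the common-partner reading forces direction-blind paths. Premotor
(postsensory) classification requires strictly more than 3 synapses onto
(from) a *single* motor (sensory) neuron; the aggregate-over-partners
variant is available behind `per_partner = FALSE`.

Cohort comparisons pool within-cohort pair values under four groupings —
HL-T cohort, hemilineage-only (same hemilineage, different temporal
cohort), temporal-only (same window, different hemilineage), and unrelated
neurons from the same hemisegment — and compare them with two-sided
Wilcoxon rank-sum tests plus two-sample Kolmogorov–Smirnov tests on the
empirical distributions; normality is pre-checked with a one-sample KS test
against a fitted normal. Cohorts with fewer than two members contribute no
pairs.

## Null models

Two connection-probability models are built per presynaptic neuron:
`input_degree` (probability of targeting j proportional to j's binarized
in-degree, identical across sources) and `overlap` (proportional to the
pre/post overlap score, with scores below a threshold zeroed; zero overlap
means zero probability). A shuffle preserves each neuron's out-degree
exactly: it redraws that many *distinct* targets without replacement with
the model's row probabilities. The test statistic is the **HL-T connection
frequency**: over all unordered within-cohort neuron pairs and all other
cohorts C, the fraction of (pair, C) combinations in which both members
send at least one edge into C (two alternative readings — per-cohort-pair
existence and per-neuron membership — are implemented behind the `reading`
flag, and the reading used is recorded in the result). The empirical
p-value uses the add-one permutation convention `(1 + #{null ≥ obs}) /
(n_iter + 1)`, which is never 0 and never exceeds 1.

**Threshold choice.** The pipeline's null analysis defaults to a
binarization threshold of 1. At threshold 1 the probability of an edge is
approximately linear in the underlying connection weight, which is the
regime in which the degree-preserving overlap shuffle is an exact null for
proximity-only data; at higher thresholds binarization becomes
superlinear in the weights while the shuffle remains linear, so even
proximity-only data drift away from the null. The stricter two-synapse
threshold remains available (`null_threshold = 2`) for analyses that want
to discount weak edges.

## The synthetic connectome generator

The generator emulates a bilateral pair of hemisegments: `n_lineages`
neuroblast lineages per side, each with a dorsal and a ventral hemilineage
and up to four temporal cohorts of `neurons_per_hlt` neurons, plus sensory
neurons (purely ventral presynapses) and motor neurons (purely dorsal
postsynapses). Defaults — 7 lineages × 2 hemilineages × 4 cohorts × 4
neurons × 2 sides (448 interneurons), with 6 sensory and 6 motor neurons
per side — approximate the scale of one reconstructed abdominal
hemisegment pair.

* **Somata and cortex lengths.** Cohort t sits at radial depth
  `t · cortex_shell_thickness / T` beyond the neuropil surface with
  Gaussian noise (`radial_noise_sd = 1000 nm` against a group spacing of
  5000 nm), so cohort means are separated by five noise standard
  deviations. Reference marker cells are drawn as Hb+ ~ N(spacing,
  spacing/2) and Cas+ ~ N(3.5·spacing, spacing): with these dispersions the
  temporal-binning rule places `t1, t2, t3` midway between the cohort
  radii, which is the geometry the rule presumes (an early marker
  concentrated below the first boundary, a late marker spanning the final
  two groups).
* **Arbors and synapse clouds.** Each hemilineage has a shared projection
  waypoint into its neuropil half — the synthetic analogue of a hemilineage
  neurite bundle — and each HL-T cohort a Gaussian synapse-cloud center
  (sd `cluster_sd = 6000 nm`) in that half; the dorsal hemilineage clusters
  its presynapses there, the ventral its postsynapses, with the opposite
  polarity drawn 2.5× more diffusely. All cohort centers share the
  segment's transverse band, giving the graded, many-neighbor overlap
  structure real arbors have rather than isolated islands. Dorsal and
  ventral centers are at least 0.35 of the dorsoventral half-extent from
  the midline; configuration fails if that separation is not more than
  twice `cluster_sd`.
* **Connectivity.** Every presynaptic site is a polyadic connector with
  `1 + Poisson(polyadic_mean − 1)` partners. Partner sets are sampled
  globally over both hemisegments with weight `overlap(i,j) ×
  (1 + ε·designated(i,j))`, in two stages: the number of distinct partners
  comes from a weighted multinomial over the partner slots, and the partner
  *set* of that size is then drawn by successive weighted sampling without
  replacement — exactly the scheme the degree-preserving shuffle uses. This
  makes proximity-only data (ε = 0) *identical in distribution* to the
  analysis' null hypothesis, which is what makes type-I-error testing
  well-posed. Defaults are sparse (presynaptic mean 8, polyadic mean 1.3,
  out-degrees around five): as in real connectomes, even strongly
  overlapping pairs often fail to connect, and the cohort statistic is not
  saturated.
* **Designated partners.** Each HL-T cohort receives
  `designated_partners_per_cohort = 4` partner cohorts, drawn uniformly
  among the cohorts it can anatomically reach without being its
  proximity-dominant partner (cohort-level overlap between 5% and 60% of
  the best partner's). The multiplicative bonus `1 + ε` on those pairs is
  the ground-truth "wiring beyond proximity" signal: designating the
  already-dominant partner would be invisible to a proximity null, and
  designating unreachable cohorts would be biologically meaningless.
* **Bilaterality.** The right hemisegment is the x-mirrored copy of the
  left with per-coordinate Gaussian jitter (`mirror_jitter_sd = 500 nm`);
  mirrored neuropil entry points are re-projected onto the neuropil surface
  so the measured entry node is the anatomical one. Connectivity is drawn
  independently per side from the mirrored geometry.

Fixtures written by `write_fixture()` contain one SWC file per neuron, the
polyadic connector table, the annotation table, the full synapse point sets
(`synapses.csv`) and `truth.json` with labels, designated pairs, reference
lengths and the configuration; everything loads back through the core
readers.

What the generator does **not** emulate: realistic neurite geometry
(tortuosity, branching statistics), irregular synapse-cloud shapes,
electrophysiology, or the circularity of real exports in which a neuron's
postsynaptic site list is exactly its contacted sites (synthetic neurons
have a latent postsynaptic site cloud from which contacts sample). Passing
recovery tests therefore demonstrates the statistical machinery under the
stated generative assumptions, not performance on electron-microscopy data.

## Problem sizes and numerical choices

The package's own validation uses three scales, chosen as the smallest that
exercise each property: unit checks run on a 2-lineage × 2-cohort × 2-neuron
connectome; parameter-recovery checks (hemilineage ARI, temporal accuracy,
similarity ordering) on the full default connectome; and the Monte-Carlo
calibration study on a reduced 3-lineage × 2-cohort configuration with 500
shuffles and 50 generator seeds per condition, which keeps a two-condition
calibration-and-power study within a coffee break while leaving the
per-condition Monte-Carlo error on the rejection rate near 4%.

Other numerical conventions: coordinates are nanometres everywhere (the
2000 nm kernel bandwidth presumes it); the axis convention is
x = mediolateral, y = dorsoventral (dorsal +y), z = anteroposterior;
autapses are rejected at load so neuron-to-neuron matrices have zero
diagonals; connector rows naming unknown neurons are dropped with a logged
count (a traced subset of a larger volume is the normal case); empty
synapse sets give overlap 0 by convention with a message; degenerate
density maps (all synapses identical) return a point mass with a warning;
and every stochastic stage accepts an explicit seed, making generator,
pipeline and null runs exactly reproducible.

## Known limitations

* The overlap kernel is O(|A|·|B|) per pair without spatial indexing;
  matrices over a few thousand neurons would need a neighbor structure.
* The null-model calibration guarantee is specific to binarization
  threshold 1; at threshold 2 the shuffle remains a sensible reference but
  is no longer an exact null even for proximity-only data.
* Temporal binning presumes the reference-marker geometry described above;
  reference sets whose dispersions do not bracket the cohort spacing yield
  boundaries inside cohorts, and the accuracy of group assignment degrades
  accordingly.
* The morphology kernel replaces empirical scoring matrices with an
  analytic form; absolute dendrogram heights are therefore not comparable
  with those of other toolchains, only the induced partitions are.
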