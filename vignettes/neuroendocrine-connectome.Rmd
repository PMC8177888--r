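---
title: "Modelling sensory-to-neuroendocrine pathways in a larval connectome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling sensory-to-neuroendocrine pathways in a larval connectome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larvaconn)
```

## The system and the questions

The *Drosophila* larva routes hormonal control through the ring gland, a
composite endocrine organ (corpora cardiaca, corpus allatum, prothoracic
gland, plus the adjoining aorta). The neurons whose axons innervate it —
ring gland projection neurons, RPNs — fall into ten peptidergic clusters
(DMS, IPCs, DH44, CRZ, ITP, CA-LP, PTTH, Hugin-RG, CAPA, EH; 56 cells in
total). Synapse-resolution electron-microscopy reconstructions make it
possible to ask, quantitatively:

* which interneurons relay peripheral sensory information (enteric,
  pharyngeal, olfactory, somatosensory, tracheal/CO~2~, terminal/ventral
  organ) onto each RPN cluster,
* how strongly a given sensory modality is expected to modulate each
  cluster, and
* which interneurons act as the dominant sensory-to-endocrine hubs.

`larvaconn` implements the full analysis chain over plain CSV neuron and
edge tables: data model and validation, input-fraction weight
normalisation, thresholded pathway analysis, a feed-forward diffusion model
of activation, hub scoring, and dense-core-vesicle (DCV) release-site
fractions — together with a seeded synthetic-connectome generator used to
exercise every stage.

## Data model and normalisation

A connectome is a neuron table (`id`, `cell_class`, optional `cluster`,
`sensory_origin`, `side`) plus a directed edge table (`pre`, `post`,
integer synapse `count`). Edge direction is presynaptic to postsynaptic
everywhere. Raw edges may repeat a (pre, post) pair; `connectome()`
aggregates them by summation, so the stored graph has at most one edge per
ordered pair. Autapses are retained but reported, since nothing in the
analysis forbids them and silently dropping data would be worse.

Synaptic weights are *input fractions*: `weight(pre, post) = count(pre,
post) / total_input(post)`. The denominator has two policies:

* `dataset_total` (default): the total is the input observed within the
  loaded connectome, so every non-isolated neuron's incoming weights sum to
  exactly 1 (asserted to 1e-12 in the tests).
* `declared_total`: the caller supplies per-neuron totals. An exported
  subnetwork typically lacks part of each neuron's input, so fractions
  against the full-volume totals cannot be recovered from the subnetwork
  alone; declared totals make worked examples with printed fractions
  encodable exactly. Declared totals must cover every neuron with observed
  input and be at least the observed sum.

Whether published input fractions were computed against full-volume or
analysed-subnetwork totals is generally not recoverable from a paper's
text; supporting both policies, with `dataset_total` as the default,
leaves that choice explicit at the call site.

## Thresholded pathway analysis

Reconstruction-grade connectivity claims use synapse-count thresholds, and
this package applies them **inclusively** (an edge of exactly the threshold
passes) and **per ordered pair** — a partner qualifies by hitting the
threshold onto a single target cell, never by pooling counts across a
group. Defaults follow the field's reconstruction practice:

| operation | default threshold |
|---|---|
| upstream partners of RPNs | 3 synapses |
| sensory → interneuron classification | 2 synapses |
| interneuron → RPN hop in 2-hop paths | 3 synapses |
| direct sensory → RPN (monosynaptic) | 3 synapses |
| hive-plot edge table | 5 synapses |

`enumerate_paths()` returns monosynaptic (length-2) and disynaptic
(length-3) paths separately with per-hop counts; no combined path strength
is defined, because any scalarisation (product, minimum, ...) is a
modelling choice best left to the caller. All tables sort lexicographically
by id so repeated runs produce byte-identical output.

Sensory profiles come in two bases: `of_total_input` divides each origin's
synapses by the subject's total input, while `of_sensory_input`
renormalises over sensory input only (the pie-chart convention, which
ignores non-sensory input to show the distribution of origins). Group
profiles pool the member neurons' input synapses — including input from
fellow members — before normalising.

## The feed-forward network (FFN) diffusion model

The FFN estimates how activating one sensory origin propagates to the RPN
clusters through mono- and disynaptic connectivity. It is a single forward
sweep — no recurrence, no inhibition, no learning:

* **Layer 0**: sensory neurons. Those of the activated origin emit a fixed
  source activity, the *activation factor* (default 2); the rest emit 0.
  Sources bypass the activation function, since that function is defined on
  input fractions and sources have no modelled input.
* **Layer 1**: every neuron directly postsynaptic to layer 0, including
  RPNs contacted monosynaptically.
* **Layer 2**: RPNs reached from layer-1 interneurons.

Each non-sensory unit receives `x = sum(weight * source activity)` over its
retained inputs and responds with a rectified linear ramp

```
f(x) = 0                  x <= a
       (x - a) / (b - a)  a < x < b
       1                  x >= b
```

with onset `a = 0.05` and saturation `b = 0.5`: units start responding when
5% of their weighted input is active and saturate at 50%. The printed
piecewise form leaves `x = a` and `x = b` open; continuity forces
`f(a) = 0`, `f(b) = 1`, which is the convention implemented and tested.
(Figure-legend phrasings elsewhere describe interneurons as "activated up
to an activity of 50%"; the equation above, whose saturation value is 1, is
what this package implements, and the discrepancy is noted rather than
resolved.) The activation factor may be set to 0, the silent limit, in
which every downstream activity is 0 — convenient as a sweep baseline.

Layering choices that were genuinely open:

* Intra-layer and backward edges (e.g. interneuron → interneuron) are
  dropped, keeping the network strictly feed-forward; dropped edges are
  reported for transparency.
* An RPN reached both monosynaptically and disynaptically is assigned to
  layer 1 but keeps its inputs from layer-1 interneurons, so both path
  lengths contribute to its drive in one evaluation — it is never
  double-counted in group means.

On a chain `s -> i -> r` with input-fraction weights `w1`, `w2`, the model
reduces to the closed form `activity(r) = f(w2 * f(2 * w1))`, which the
test suite checks across weight settings. Other tested invariants:
non-sensory activities always lie in [0, 1]; activities are monotone in any
single weight and in the activation factor; joint activation of two origins
dominates either alone.

`mean_group_activity()` averages over cluster members, counting members
unreachable from the active origin as 0 — a cluster is not "activated" by
the reachability of one cell.

## Hub score and DCV fractions

The hub score of an interneuron with respect to an RPN group is

```
score = frac_sensory_in * frac_to_rpn
```

where `frac_sensory_in` is the fraction of the interneuron's total input
contributed by sensory neurons and `frac_to_rpn` is the fraction of the
group's *pooled* total input contributed by that interneuron (a per-cell
variant is available via `per_cell = TRUE`). Both fractions are computed by
summing integer synapse counts before a single division, so fixtures built
from integer counts reproduce printed four-decimal fractions bit-exactly;
scores are invariant under global rescaling of all counts. The packaged
worked example (`worked_example_fixture()`) encodes an interneuron with
sensory-input fraction 0.3233 supplying 0.5652 of a two-cell CRZ-analog
group's input, with declared totals of 10 000 synapses, giving the top
score 0.3233 × 0.5652 = 0.18272916.

`dcv_fractions()` converts counts of membrane-fused dense-core vesicles —
peptidergic release sites annotated per ring gland tissue (CC_AO, CA, PG) —
into per-group fractions that sum to 1. Release sites within the CNS are
out of scope; only ring gland tissues are typed.

## The synthetic-connectome generator

`simulate_connectome()` draws seeded random connectomes with the
statistical structure the analysis assumes, so every operation can be
exercised at realistic scale without the (unpublishable-in-text) full EM
adjacency:

* RPN census fixed at the study's values: DMS 4, IPCs 14, DH44 6, CRZ 6,
  ITP 8, CA-LP 6, PTTH 4, HugRG 4, CAPA 2, EH 2 (56 cells, 10 clusters).
* 209 interneurons, matching the reconstructed upstream-partner count.
* Sensory census: 26 CO~2~-responsive tracheal dendritic neurons (the one
  origin with a published census); the other five origins default to 30
  cells each, a plausibility-level even split.
* Edges drawn per eligible pair: sensory→interneuron and interneuron→RPN at
  `edge_density` (default 0.02), sensory→RPN at a quarter and
  interneuron→interneuron at half of that — both sparse in the data.
* Synapse counts follow `1 + Geometric(mean = 6)` truncated at 150,
  matching the observed heavy right skew (connections of 1 to ~150
  synapses; strongest observed 147). The law is configurable; no published
  distribution exists, so the default is a documented choice, and the test
  suite checks the empirical CDF against the closed form at n > 10^4 draws.
* Background and motif planting use separate derived random sub-streams, so
  adding a motif never perturbs background edges, and the same seed yields
  a byte-identical connectome.

`plant_pathway()` overlays a strong sensory-to-endocrine motif: by default
4 core interneurons each receiving 6 strong CO~2~ inputs (counts 60–150)
and projecting with such counts onto every member of the DH44 and CRZ
clusters — the structure of the CO~2~ pathway through thoracic
interneurons. The planted-pathway property asserts that, over 100 seeded
generations, DH44 and CRZ rank in the top 2 clusters by mean FFN activity
under CO~2~ activation in at least 95.

What the generator does **not** emulate: hemilateral mirror-symmetric
pairing of connections, realistic in/out-degree distributions (unpublished
at usable granularity), distance-dependent connectivity, or the real
adjacency matrix itself. Passing tests on synthetic data therefore
demonstrate correctness of the *operations* and recoverability of planted
structure, not agreement with the biological network; quantities that
depend on the full EM volume (e.g. a cluster's total synaptic load from
sensory-connected interneurons) are computed by the same code paths but can
only be asserted on fixtures.

## Numerical and reproducibility choices

* Fractions from integer counts are computed as `sum(counts) / total` (one
  division), never as sums of per-edge weights, avoiding an
  ulp-level accumulation error.
* All tables sort lexicographically (radix, locale-independent); pipeline
  outputs format floating numbers at 9 significant digits and carry a
  parameter header, so reruns diff byte-identically.
* The generator saves and restores the caller's RNG state.
* Test problem sizes: oracle-equivalence runs use 100 random 30-node
  connectomes against brute-force scans; FFN property checks use 20 random
  networks plus closed-form chains; the planted-pathway property uses 100
  default-size generations (441 neurons each). These sizes give the
  properties room to fail while keeping the default suite fast.

## Command-line pipeline

The same stages are scriptable via the thin wrapper installed at
`system.file("cli", "larvaconn.R", package = "larvaconn")` with subcommands
`simulate`, `analyze`, `ffn` and `dcv`, a YAML config (flags > file >
defaults), logging to stderr, and exit codes 0 (success), 2 (validation
failure), 1 (unexpected error).

## Known limitations

* Connection signs are ignored: the FFN treats every synapse as excitatory,
  so predicted activations are upper-bound-style estimates of modulation,
  not signed responses.
* Propagation depth is capped at two hops; deeper polysynaptic routes are
  outside the model.
* The hub score is a product of two static fractions; it does not account
  for interneuron excitability or peptide identity.
* Left/right `side` annotations are carried but never used for automatic
  mirroring or pair pooling.
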