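---
title: "Methods: focused-array ratio processing, kinetic modes, UPGMA and key-node search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: focused-array ratio processing, kinetic modes, UPGMA and key-node search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytoarray)
library(dplyr)
```

## The problem this package addresses

Comparative functional genomics of anti-inflammatory phytocompounds asks a
simple question with a layered analysis behind it: when LPS-stimulated
monocytes (the THP-1 model of macrophage activation) are co-treated with a
candidate compound — shikonin, emodin, cytopiloyne, or a defined
*Echinacea purpurea* extract (BF/S+L/Ep) — which immune genes change, with
what kinetics, and which upstream signaling molecule could account for the
coordinated change?

The measurement platform is a focused two-color DNA microarray: 228
immune-function genes, four replicate spots each, five housekeeping genes
as internal controls. Each chip hybridizes a Cy5-labelled test sample
against a Cy3-labelled control sample, so the per-gene readout is a linear
test:control expression ratio. `phytoarray` implements the full downstream
chain as tidy, pipeable functions: spot tables in, ranked master-regulator
candidates out.

## Ratio processing

The chain from spot intensities to a gene-by-condition ratio matrix is:

1. **Background correction** — `background_correct()` computes
   `max(fg − bg, 1)` per channel. The quantification software that produces
   spot tables does not dictate a correction; subtraction with a floor of 1
   intensity unit is the simplest rule that keeps every downstream ratio
   finite and strictly positive. The floor only binds when background
   swamps signal, in which case the spot carries no usable information
   anyway.
2. **Per-spot ratio, then replicate aggregation** —
   `aggregate_replicates()` takes the **median** of the (up to four)
   unflagged replicate spot ratios. The platform convention of reporting a
   "median of ratio" per spot is a pixel-level statistic we do not model;
   across replicate spots the median is the robust choice, and the mean is
   available as an option. A gene whose replicates are all flagged is
   reported missing for that chip and excluded from filtering and
   clustering, with a logged count.
3. **Housekeeping normalization** — `normalize_to_reference()` divides
   every gene's ratio in a condition by the reference gene's ratio in the
   same condition. The default reference is beta-actin (ACTB), the
   conventional choice and the first-named internal control; any
   housekeeping-flagged gene can be selected instead (the five controls on
   the design are alpha-tubulin, B2M, beta-actin, GAPDH and transferrin
   receptor). After normalization the reference row is exactly 1 in every
   condition, and the operation is idempotent — both properties are tested
   exactly, not to a tolerance.
4. **Ratio semantics** — on chip designs where every sample is hybridized
   against vehicle, the compound effect relative to LPS is formed as a
   ratio of ratios, `(compound+LPS : vehicle) / (LPS : vehicle)`, by
   `treatment_vs_lps()`. On designs where compound chips hybridize
   directly against LPS-only samples the chip ratio is already the
   treatment:LPS ratio. Both are supported
   (`ratio_semantics = "vehicle_ref"` / `"lps_ref"`).

### The fold-change rule

`filter_fold_change()` retains a gene as *up* when its ratio is `>= T` and
as *down* when it is `<= 1/T`, with `T = 3` by default — i.e. expression
above 300% or below 33% of the comparison sample. Comparisons are
inclusive and made at full float precision; the transcribed tables print
two decimals, and 0.33 ≤ 1/3 holds, so printed boundary values are
retained. The rule is evaluated over a selected treatment set under an
any/all quantifier, and hit tables are sorted by functional category and
then Entrez gene id, mirroring the published table layout. There is no
moderated statistic here by design: the method is a pure fold-change
screen, and the package deliberately reproduces that.

## Kinetic regulation modes

Treatment:LPS profiles over the 0.5/2/4/12/48 h grid are classified on the
log2 scale. A gene's direction at a time point is *down* at or below
`-theta`, *up* at or above `+theta`, and *none* otherwise. Modes are
assigned by precedence at three anchor times — early (0.5 h), delayed
(2 h), and the up-regulation point (4 h):

1. `EARLY_DOWN_THEN_UP`: down at 0.5 h and up at 4 h;
2. `DELAYED_DOWN_THEN_UP`: not down at 0.5 h, down at 2 h, up at 4 h;
3. `EARLY_NONE_THEN_UP`: no response at 0.5 h and up at 4 h;
4. `OTHER`: everything else — a residual class, exactly as the original
   analysis treats it.

Two parameters here are genuinely open and were fixed once:

* **`theta = log2(1.5) ≈ 0.585`.** The source analysis never quantifies
  "down/up/non-response". A 1.5-fold excursion separates real responses
  from the multiplicative spot noise the simulator assumes (sigma = 0.1 on
  the natural-log scale, i.e. about 0.2 in log2 units after replicate
  aggregation) while staying far below the 3-fold hit threshold. It is a
  configurable argument everywhere it appears.
* **Anchor times** (0.5/2/4 h) follow the narrative structure of the
  time course — onset, delayed repression, predominant up-regulation —
  and are also configurable.

A profile that is *none* at 0.5 h, *down* at 2 h and *up* at 4 h satisfies
both the delayed-down definition and a loose reading of early-none; the
delayed-down class takes precedence so that the four classes partition the
genes, which the published grouping implicitly assumes.

The LPS-only baseline direction (`classify_baseline()`) tags each gene
*up* or *down* from its LPS-vs-vehicle profile: by the first time point
when it clears `theta`, otherwise by the sign of the largest-magnitude
excursion anywhere in the profile; an exactly flat profile resolves to
*up* (the tie is arbitrary and documented rather than hidden).

**Concordance** between treatments is the percentage of the reference
treatment's mode group that the other treatment places in the same mode,
rounded half-up to one decimal — the convention under which 17/23 prints
as 73.9%. Base R's round-half-to-even would print 73.9 or 74 depending on
floating-point representation, so the package implements the half-up rule
explicitly.

## UPGMA clustering

`upgma()` implements the classic unweighted pair-group method: repeatedly
merge the two closest clusters, with the distance from a merged cluster to
any other equal to the size-weighted average of its members' distances
(equivalently, the plain mean over all member pairs of the original
distances). Three choices were open:

* **Distance metric.** The source clusters log2 ratio profiles but does
  not name a metric. The default is Euclidean distance on log2 ratios;
  1 − Pearson correlation is offered for shape-based clustering. Pearson
  errors out on constant profiles rather than silently producing NaN.
* **Tie-breaking.** When several pairs share the minimum distance, the
  pair whose clusters contain the smallest original item indices merges
  first. Continuous data never ties, but fixture data printed to two
  decimals can; determinism matters more than any particular choice.
* **Leaf order and export.** At every merge the child containing the
  smaller original index is drawn on the left, giving a deterministic
  heat-map ordering. `to_newick()` exports the ultrametric convention:
  each merge node sits at half its merge distance, so leaf-to-leaf path
  lengths equal cophenetic distances.

The returned object inherits from `hclust`, so `stats::cophenetic()`,
`stats::cutree()` and standard dendrogram plotting work unchanged; the
test suite uses `stats::hclust(method = "average")` and a literal O(n³)
re-implementation as independent oracles.

## Key-node (master-regulator) search

Given a signed directed signaling network (three-column SIF-like TSV:
source, `activate`/`inhibit`, target) and a set of regulated query genes,
`find_key_nodes()` scores **every node** as a candidate upstream
regulator:

* **Coverage** is the fraction of mapped query genes reachable within
  `max_depth` directed steps (default 4, *inclusive* — the narrative
  description "no more than 4 steps" is taken as primary over a figure
  legend that says "less than four"). Paths must contain at least one
  edge, so a query gene never covers itself at depth 0.
* **Full-coverage nodes** are the "common denominators" of the gene set;
  by default only these are returned, and an empty result is reported
  explicitly rather than silently.
* **Ranking**: coverage (descending), then maximum depth, then mean depth
  (both ascending — shallower regulators are more parsimonious), then
  node id in a locale-independent lexicographic order for determinism.
* **Sign consistency** annotates each candidate. Along every shortest
  path the edge signs multiply (an even number of inhibitions nets out to
  activation). Under an assumed regulator state — active/up or
  inactive/down — each achievable net sign predicts a direction for the
  covered gene; a gene is consistent when any of its shortest paths
  predicts its observed direction, and the candidate reports the better
  of the two states. Consistency is an annotation, not a filter: the
  published figures mix activating and inhibiting edges without stating
  a sign filter, so filtering on it would overcommit.

The search itself is a truncated breadth-first search per candidate
(`bounded_reach()`), tracking the set of achievable net signs at each
node's shortest depth. Proprietary pathway databases are not consumed;
networks are user-supplied or simulated.

## The synthetic-data generator

`simulate_experiment()` emulates the study conditions: 228 genes, 5
housekeeping controls, 4 replicate spots, treatments {LPS, shikonin,
emodin, cytopiloyne, BF} and the 0.5/2/4/12/48 h grid. Per-gene baseline
abundances are drawn log-uniformly over 50–5000 intensity units so that
background flooring is actually exercised at the low end; a constant
background of 100 units is added to the foreground and reported in the
background columns. Each channel's signal is multiplied by independent
log-normal noise (`noise_sigma`, default 0.1 on the natural-log scale —
a typical spot-level CV of ~10% for a two-color platform); the test
channel is additionally multiplied by the planted linear effect.
Housekeeping genes always carry effect 1, so their processed ratios have
expectation 1 in every condition. The seed fully determines the output.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: dye-specific (intensity-dependent) bias that
loess normalization would target, spatial artifacts on the slide,
correlated noise between channels of one spot, cross-hybridization, and
any biological covariance between genes. The generator validates the
pipeline's arithmetic and its operating characteristics under the stated
noise model, nothing more.

`simulate_network()` plants a master regulator wired to every query gene
at an exact configured depth (1–4) through fresh intermediate nodes, adds
distractor regulators wired directly to strict subsets of the query (at
most 7 of 10 by default), and fills the graph to ~200 nodes with random
edges **among the filler nodes only**. Filler edges never target the
planted scaffold or the query genes; this keeps the config's invariant —
distractor coverage strictly below 1 — true by construction rather than
with high probability, so recovery failures in tests would indicate real
defects rather than unlucky wiring. Each query gene's observed direction
is the direction its planted chain predicts when the regulator is active,
making the planted node fully sign-consistent.

## Packaged fixtures

The three published ratio tables are transcribed verbatim (45, 16 and 30
rows; treatment:LPS ratios at 0.5, 4 and 12 h respectively) and every row
satisfies its table's fold rule at the printed precision. The figure
networks are a different matter: the published figures convey their
topology graphically and no machine-readable version exists, so the
packaged networks (`*_synthetic.tsv`) are **synthetic reconstructions**
that preserve only the qualitative claim of each figure — that ERK1/2,
Rad23A, E6-AP and Lck are the sole full-coverage key nodes at depth ≤ 4
over their respective regulated gene sets, with plausible signed
intermediates. They support topology-level tests and worked examples,
never numeric claims.

## Numerical and testing choices

* Inclusive thresholds throughout (`>= T`, `<= 1/T`; `<= -theta`,
  `>= theta`); full float precision everywhere except the printed-percent
  convention above.
* All orderings (hit tables, rankings, tie-breaks, leaf order) are
  deterministic and locale-independent (`method = "radix"`).
* Problem sizes in the test and acceptance suites were chosen to give
  stable statistics at interactive runtimes: 200 random distance matrices
  (n ≤ 8) against the brute-force UPGMA oracle; 100 seeded ~200-node
  networks for planted-regulator recovery; 50 seeded spike-in experiments
  (20 planted genes at 4-fold or 0.25-fold, sigma = 0.1) for filter
  sensitivity and false-discovery proportion, plus a noise-free run that
  must recover the planted set exactly.
* The acceptance script (`scripts/acceptance.R`) recomputes all of these
  from scratch under a caller-supplied seed.

## Known limitations and open questions

* "β-actin (B2M)" in the source conflates two distinct housekeeping genes
  (beta-actin is ACTB; B2M is beta-2-microglobulin). The package defaults
  to ACTB and lets the user pick any housekeeping gene; the ambiguity is
  surfaced, not resolved.
* The source narrative says "approximately 50 genes" where its first
  table lists 45 rows; the fixture encodes the 45 printed rows.
* The published heat map shows 191 of 228 genes without stating the
  inclusion rule; the package clusters all genes with complete profiles.
* The 48 h arrays are described but not tabulated; the package assumes
  the same processing applies.
* No dye-swap, loess or quantile normalization, no per-spot pixel
  statistics, and no moderated differential statistics — the analysis
  this package implements is a housekeeping-normalized fold-change
  screen, and the package is faithful to that scope.
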