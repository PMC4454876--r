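---
title: "Predicting protein interaction networks from interologs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protein interaction networks from interologs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(interologr)
```

## The model

The interolog method rests on one assumption: if an interaction
existed in the last common ancestor of two species and both proteins
were retained after divergence, the interaction tends to be retained
too. Operationally, an experimentally observed interaction (r₁, r₂) in
a reference species is transferred to the target species wherever both
endpoints have orthologs there: with target ortholog sets T₁ and T₂,
every pair in T₁ × T₂ becomes a prediction. The assumption weakens
with evolutionary distance and with gene duplication — an inparalog
that subfunctionalized may not inherit its sibling's partners — which
is why the package keeps two mapping schemes side by side:

* **one-to-one** uses only each cluster's seed pair (inparalog score
  1.0 *and* bootstrap 100 on both sides), the strictest orthology
  statement available from pairwise clustering;
* **many-to-many** expands every cluster into its full member cross
  product, admitting inparalog substitution. Outparalogs live in
  separate clusters and never substitute.

In this implementation the seed pair is always one of the expanded
pairs, so the one-to-one prediction set is contained in the
many-to-many set by construction. Published interolog interactomes do
not always have this property (their pipelines were run
independently per scheme); `merge_and_partition()` therefore accepts
arbitrary independently built sets and computes the scheme partition
without assuming containment.

## Confidence scoring

Each deduplicated prediction is scored `CV = N × S × E`. The three
counts are deliberately asymmetric in what they measure:

* `N` — distinct (reference species, canonical reference pair, source
  database) support tuples: raw evidence volume, including the same
  physical experiment surfacing in several databases;
* `S` — distinct reference species: evolutionary breadth;
* `E` — distinct experimental method labels: methodological
  independence, because different assays have non-overlapping
  false-positive profiles.

Informal definitions of these counts are circular in parts of the
literature; the tuple definitions above were chosen so that `N ≥ S`
always holds, which gives the useful anchor that an interaction
supported once in each of four species under one method scores exactly
4 × 4 × 1 = 16 — and, more generally, `CV ≥ S²`. Bins are defined on
integers: CV = 1 low, 2–10 medium, > 10 high. Whether to count method
labels per database record or per publication is not settled usage;
the package counts distinct labels per merged prediction and documents
it as a convention.

Reference pairs are canonicalized per species *before* support
counting, so a database row and its mirror image are one reference
pair; target pairs are canonicalized with the larger identifier first
(strict byte-order comparison, locale-independent). Self-interactions
are legal predictions and flow through scoring unchanged.

## Network analysis

Degree counts *distinct partners*, with a self-loop contributing one
(the node is its own partner once) — not edge multiplicity. Hub
classes: > 10 partners highly connected hub, 3–10 small hub, 2 pipe,
1 free end, 0 isolated (the last an extension for completeness;
isolated nodes are dropped from subnetwork outputs and reported in
logs).

Characteristic path length is the mean shortest-path length over
unordered pairs of distinct, mutually reachable nodes across the whole
graph, not only the giant component; unreachable pairs cannot
contribute a finite length and are excluded rather than imputed.
Self-loops never shorten a path and are ignored. The power-law
diagnostic is an ordinary least-squares line on (log₁₀ degree,
log₁₀ frequency) over degrees ≥ 1 — transparent and testable, though
statistically cruder than maximum-likelihood exponent estimation; it
is reported as a qualitative check of the inverse power relationship,
not as a calibrated estimate. A perfectly flat histogram has zero
variance to explain, so its R² is defined as 1 with exponent 0.

## Co-expression support

Expression support uses M-values, `M = log₂(treatment/control)`, over
a compendium of contrasts (the generator's default of 68 mirrors a
typical stress-microarray compendium). Choices a user should know:

* *Global intensity normalization* is defined as scaling each sample
  column to the grand-mean column total — the simplest reading of the
  name; pre-normalize differently if needed and read in `m_values`
  mode.
* Intensities are floored at 1.0 before the ratio to keep
  near-zero spots finite.
* The protein → gene map defaults to stripping a trailing protein-model
  suffix (`_P01`-style); supply an explicit mapping otherwise.
* The correlation is the raw-sums computational form of Pearson's r,
  clamped to [−1, 1] against floating-point drift; zero-variance
  profiles return an undefined flag, and undefined correlations are
  excluded from tests, never imputed.
* The observed-vs-null comparison defaults to Welch's unequal-variance
  t-test: there is no natural pairing between an edge and a random
  non-edge, so a paired test is not meaningful as a default. The
  paired mode is retained for fidelity to older workflows and flagged
  in the output. The null samples distinct non-edge pairs uniformly
  without replacement, seeded explicitly.
* The 68 contrasts are treated as one concatenated profile per gene
  (not correlated per-dataset and combined) — a documented convention
  where usage varies.

## Enrichment and overlap validation

GO enrichment compares a foreground (e.g. interactome proteins)
against a background (e.g. the annotated genome) per term with both
one-sided hypergeometric tails, inclusive of the observed count; the
smaller tail is reported with its direction, and Benjamini–Hochberg
FDR (α = 0.05 by default) is applied across terms. Annotations are
used flat; `propagate_annotations()` closes them over a child→parent
table for users who want ancestor-propagated tests, but it is off by
default because plugin behaviours differ and silent propagation
changes counts.

Overlap validation restricts both interaction sets to their `V`
common proteins, among which `P = (V² + V)/2` unordered pairs are
possible — self-pairs included, a quote-faithful choice. Expected
overlap is the hypergeometric mean `n_a·n_b / P` (a closed form;
Monte-Carlo simulation exists only as a test oracle). The chi-square
uses the 2-cell partition {overlap, non-overlap} of the first set's
restricted pairs, 1 df, no continuity correction — the simplest
reading of a "1-degree-of-freedom chi-square"; with large expected
counts the correction is immaterial, and the report prints all inputs
so any other test can be applied downstream.

## The synthetic generator

The generator emulates the *structure* of real inputs with planted
ground truth: two-species clusters with seed members and optional
inparalogs; a configurable fraction of clusters failing the
bootstrap-100 criterion (contributing to many-to-many only); reference
interaction sets planted per profile row with exact
(S, E, multiplicity), so each planted pair's CV = (S·multiplicity)·S·E
is known in advance; expression profiles sharing a per-edge latent
factor giving expected correlation ρ; and an annotation universe with
one term enriched a chosen fold among null terms.

Defaults are study-scale-realistic rather than genome-scale: 4
reference species (up to 13 supported, matching the breadth a real
panel offers), 50 target proteins, inparalog rate 0.3 (recent
polyploids are paralog-rich), bootstrap failure rate 0.1, ρ = 0.8 at
68 contrasts, 5×-enriched term at foreground 200 / background 2000.
What the fixtures deliberately do **not** model: sequence evolution,
correlated database redundancy, study bias in method labels,
heavy-tailed microarray noise, or GO's DAG structure. Passing tests
therefore demonstrate algorithmic correctness — exact recovery of
planted evidence, set identities, oracle agreement — not predictive
accuracy on real proteomes, which is bounded by the quality of the
upstream clusters and reference interactomes.

## Numerical and degenerate-input choices

* Identifier comparison is strict byte order via a hex sort key, so
  canonical ordering does not depend on the session locale.
* Seed-pair ties (several members at score 1.0 / bootstrap 100) break
  to the lexicographically smallest id — deterministic where the
  underlying convention is silent.
* Readers never drop rows silently: `on_error = "stop"` names the
  offending line; `on_error = "skip"` logs line numbers and keeps the
  row-count identity (rows in = records out + rejected).
* Fold changes print at nine decimal places in summaries; undefined
  ratios (zero denominators) are reported empty, not as infinities.
* Monotone guarantees are tested as properties: conservation filtering
  is nested in its threshold, transfer is insensitive to row order and
  endpoint swaps, and scoring is a pure function of the support set.

Test problem sizes were chosen to keep the full suite fast on a
laptop-class single core while leaving the statistical checks
well-powered: universes of 20–50 target proteins and 2–5 reference
species, graphs up to 200 nodes for the exhaustive path-length oracle,
100,000 Monte-Carlo draws for the overlap model, 100 seeded replicates
for the planted-enrichment ranking, and exhaustive hypergeometric
enumeration over all universes up to size 12.

## Limitations

Prediction quality is inherited: ortholog clustering errors, database
redundancy and reference-interactome false positives propagate into
CV. The method under-predicts lineage-specific interactions by
construction — a target-only signaling rewiring is invisible to
transfer from distant references. CV is an evidence count, not a
calibrated probability; comparing CVs across datasets with different
reference panels is not meaningful. Finally, co-expression is support,
not proof: physically interacting proteins need not be co-regulated,
and the package reports the comparison rather than filtering on it.
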