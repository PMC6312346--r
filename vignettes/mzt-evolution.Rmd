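---
title: "Comparative analysis of maternal and zygotic transcript complements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative analysis of maternal and zygotic transcript complements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

During the maternal-to-zygotic transition (MZT), control of early animal
development passes from maternally deposited mRNA to transcripts made by
the zygote's own genome. Comparing embryo transcriptomes sampled just
before zygotic genome activation ("stage 2" in *Drosophila* staging, all
transcripts maternal) and just after cellularization completes ("stage
5", a mixture of surviving maternal transcripts and new zygotic ones)
across a clade of species asks how evolutionarily labile maternal
deposition and early zygotic transcription are, and which genes keep a
stage-restricted state over tens to hundreds of millions of years.

`mztevol` implements that comparison as a reusable pipeline over
isoform-level FPKM tables: six-way stage classification of isoforms and
genes, detection of stage-specific alternative isoform usage, cross-
species correlation and clustering on one-to-one orthologs, ancestral
reconstruction of transcript presence/absence on a fixed phylogeny with
gain/loss calling, and identification of core conserved stage-restricted
gene sets against a distant outgroup. A ground-truthed simulator
generates complete datasets with the same statistical structure, so every
stage of the pipeline is testable without any sequencing data.

## Stage classification

Presence is a threshold rule: a feature is present at a stage when its
mean replicate FPKM is at or above 1 (the threshold is configurable via
`classifier_config()`; the inclusive boundary matters and is tested).
Each feature gets exactly one of six categories:

* **N** — below threshold at both stages;
* **M** (maternal-only) — present at stage 2 only;
* **Z** (zygotic-only) — present at stage 5 only;
* **PM / PZ** (predominantly maternal / zygotic) — present at both
  stages, at least 2-fold higher at one stage, and significantly
  different between stages (BH-adjusted q < 0.05);
* **MZ** — present at both stages, predominant at neither.

The fold condition is inclusive (a ratio of exactly 2 qualifies) and a
feature whose significance is untestable (fewer than two replicates at
either stage) can never be PM or PZ.

The original analyses took significance from read-level differential
tests. Read-level data are not part of this pipeline's inputs, so
`stage_significance()` defines a replicate-level stand-in: a two-sided
Welch t-test on log2(FPKM + 1), BH-adjusted across all features of a
species. This is deterministic and computable from the FPKM tables
alone, but it is *not* numerically identical to a negative-binomial
read-count test; with three replicates per stage it is somewhat more
permissive for large fold changes. An exact label-permutation test on
the difference of log2 means is available (`method = "permutation"`) for
small replicate counts; note that with 3 + 3 replicates its smallest
achievable two-sided p is 0.1, so the Welch test is the default.
Replicate sets with zero variance at both stages are resolved
definitionally (p = 1 when the means coincide, p = 0 otherwise), which
makes the noiseless limit exact.

A gene's category is computed from the sum of its isoforms' FPKM, never
by combining isoform categories; a gene can be present while every
isoform is individually sub-threshold. A gene is **ALT** when at least
one isoform is maternal-class (M or PM) and another is zygotic-class
(Z or PZ) — the signature of stage-specific isoform usage.

## Cross-species comparison

Correlations between species use Spearman's rank coefficient on mean
FPKM over one-to-one ortholog groups (groups with a blank entry in
either species of a pair are excluded pairwise). Restricting to a
category can be done two ways, and the distinction is scientifically
meaningful: `shared_in_both` keeps genes with the category in both
species (the conserved subset), `in_either` keeps genes with the
category in at least one. A constant vector has an undefined rank
correlation; it propagates as `NA`, never as 0.

Clustering of the species-by-stage condition transcriptomes uses
`stats::hclust` with average linkage on the distance 1 − ρ. The metric
and linkage were a free choice (the original tool default is not
recorded); both are pinned and stamped on the result so the dendrogram
is reproducible. On data with stage-structured expression the top split
separates the two stages — the qualitative signature the pipeline's
acceptance checks assert.

## Ancestral reconstruction of transcript presence

For each ortholog group and stage, every species is coded 1 (mean FPKM
at or above the threshold), 0 (below), or unknown (blank ortholog), two
characters per gene. Characters evolve under a two-state continuous-time
Markov model with gain rate q01 and loss rate q10 per unit branch
length; transition probabilities over a branch of length t use the
closed form with r = q01 + q10:

    P(0→1) = q01 (1 − e^{−rt}) / r,   P(1→0) = q10 (1 − e^{−rt}) / r.

Likelihoods come from Felsenstein's pruning algorithm
(`pruning_likelihood()`), vectorised over characters with per-node
rescaling so thousands of characters are computed at once without
underflow. Unknown tips contribute a partial likelihood of (1, 1).

Rates are estimated by maximising the summed log-likelihood of all
characters of a stage (`fit_rates()`, L-BFGS-B on log rates, bounded in
[1e-6, 1e3] with a warning if a bound is hit, identical site patterns
collapsed with weights). One rate pair is shared by all characters of a
stage: single binary characters cannot identify per-character rates, and
a single shared partition mirrors how a binary-model MCMC would treat
the data. The root prior is the stationary distribution of the fitted
rates, which leaves no free root parameter (empirical Bayes).

Node posteriors are exact marginals from the standard up-down
(inside-outside) pass (`marginal_posteriors()`), checked against
brute-force enumeration over all internal-state assignments on small
trees to 1e-10. This replaces the MCMC reconstruction used originally:
on a fixed tree the marginals are computable exactly, which removes
Monte Carlo noise from the event calls; the posterior-threshold event
logic is unchanged. (For the same reason no MCMC sensitivity mode is
provided — with the tree fixed there is nothing left to average over
except the two rates, whose likelihood surface is sharply peaked at
thousands of characters.)

A **gain** is called on a parent→child branch when the parent is absent
with posterior ≥ 0.90 and the child present with posterior ≥ 0.90; a
**loss** is the mirror image. Observed tips count as posterior 1 on
their state, so terminal branches are eligible (species-level gains are
reported in the motivating study); branches ending in an unknown tip are
skipped. Both choices are flags on `call_transitions()`. Raising the
threshold can only remove events (tested property). The threshold
semantics are deliberately strict: only transitions between adjacent
nodes at 90/90 are called, and a lower threshold must be requested
explicitly.

Two parsimony baselines support testing: first-pass Fitch counting
(`fitch_parsimony()`) and exact most-parsimonious state sets by the
Sankoff up-down recursion (`mpr_state_sets()`). These differ: the
first-pass set at a node need not coincide with the states realised by
minimum-change reconstructions. In the low-rate limit (rate × tree
height ≤ 1e-4) the maximum-posterior state matches the unique
most-parsimonious state essentially always — the MPR sets, not the
first-pass sets, are the correct comparator, because with branch lengths
varying the posterior weights minimum-change reconstructions by where
on the tree the changes fall.

## Conservation against a distant outgroup

For a category (zygotic-only by default), the **loose** conserved set
contains genes with the category in the outgroup and at least one
ingroup species; the **core** set requires the outgroup, the basal
ingroup species, and at least one member of the other subgenus — three
deeply separated observations. Core ⊆ loose by construction.
`mean_additional_species()` reports how many *other* ingroup species
share the category: the species used as membership criteria are excluded
from the count (two for the core set — the basal species and one
qualifying subgenus species — one for the loose set), and species with
unknown state are excluded from numerator and denominator alike, since
an unknown ortholog carries no evidence either way. The machinery is
category-agnostic; maternal-only conservation uses the same functions.

## The simulator and what it emulates

`simulation_config()` fixes the reference study conditions; its defaults
are chosen once, from the structure of the motivating data, and define
what "the default fixture" means throughout the tests:

| parameter | default | rationale |
|---|---|---|
| tree | bundled 14-tip phylogeny | clade structure of the study system: a melanogaster-like subgroup with two sister pairs, an obscura-like clade, a basal tip, a two-species distant subgenus; unit-free lengths |
| q01, q10 | 0.5, 0.1534 | stationary presence probability 0.765; with 6.56% unknowns this reproduces overall state frequencies ≈ 0.715 / 0.219 / 0.066 |
| n_genes | 2000 | enough for stable rate fits and event counts at desk scale |
| present FPKM | lognormal, median 20, log-sd 1 | typical expressed-gene FPKM scale; floored at 2 so presence survives replicate noise |
| bm_sd | 0.3 per unit branch length | Brownian divergence of log-level, so correlation decays with patristic distance |
| replicate_cv | 0.2 | single-embryo replicate reproducibility (within-stage ρ ≈ 0.95) |
| n_replicates | 3 | the study's minimum replication |
| missing_rate | 0.0656 | the unknown-state frequency of the real character matrix |
| leak_prob / leak_max | 0.1 / 0.5 FPKM | real "absent" genes show trace FPKM; exercises the presence boundary |
| alt_fraction | 0.1 | upper end of the observed 4–10% ALT-gene range |
| PM/PZ fractions | 0.15 / 0.15 | designed fold ratios 3.5–6×; MZ ratios inside (0.75, 1.33) |

Genes present at both stages are assigned a subclass with designed
stage ratios kept away from the 2-fold boundary on both sides. This is
deliberate: the six-way rule is a partition with a hard boundary, and a
simulator that placed true ratios arbitrarily close to 2 would make
"fraction of correct categories" measure boundary density rather than
classifier correctness. Truth labels are the definitional rule applied
to the designed (noise-free) means, so at `replicate_cv = 0` and zero
leak the pipeline must recover every label exactly — and does, which is
itself an acceptance check.

ALT genes carry one purely maternal and one purely zygotic isoform;
non-ALT genes split their level across 1–3 isoforms with stage-constant
proportions, which makes a false ALT call impossible on noiseless data
(all isoforms of a gene share its stage ratio) and measurably rare
(≤ 1%) under noise. The two stage characters of a gene evolve
independently; the motivating observation is that simultaneous
two-stage transitions are rare, and independence is the simplest
structure consistent with that. A distant outgroup species is evolved
from the root along a long branch (default length 1.0) and runs through
the same expression machinery, standing in for the basal-Dipteran
comparison; it is synthetic, like everything else the simulator emits.

What the simulator does **not** emulate: read-level sampling noise and
its mean–variance relation (FPKM noise is lognormal, not NB-derived),
upper-quartile normalisation artefacts, correlated gene modules,
lineage-specific rate variation, annotation quality differences between
species, and sex-specific expression. Passing recovery tests therefore
demonstrates that the pipeline's logic is correct under its stated
model, not that the thresholds are optimal for any particular real
dataset.

## Numerical choices

* Pruning partials are rescaled by their row maximum at every internal
  node; log scale factors accumulate into the log-likelihood. Impossible
  data (conflicting states across zero-length branches) give −Inf, not
  an error.
* Rate optimisation runs on log rates; a non-finite likelihood during a
  step returns a large penalty rather than aborting.
* (rate × c, length / c) leaves likelihood and posteriors invariant —
  branch lengths are unit-free, and the invariance is tested to 1e-12.
* Spearman of a constant vector is `NA`; Fisher's odds ratio adds 0.5 to
  every cell only when a cell is zero, and a 2×2 table with an empty
  margin yields p = 1 with a warning. Fully tied rank-sum comparisons
  yield p = 1.
* Determinism: a fixed `seed` in `simulation_config()` makes fixtures
  byte-identical; `run_pipeline()` stamps a configuration hash into its
  manifest so identical runs are recognisable.

## Problem sizes

The shipped tests and the acceptance script run entirely on simulated
data at sizes chosen to make every check sharp but quick: 2,000-gene
datasets for recovery and calibration (about 48,000 confident node
calls), 8,075 ortholog groups for the character-count arithmetic,
100 random 3–6-tip instances against the enumeration oracle, 1,000
6-tip characters for the parsimony limit, 10,000 fuzzed classifier
inputs, and all 46,375 2×2 tables with total count ≤ 30 against the
hypergeometric enumeration. The `analysis/` scripts use the same
defaults and finish in well under a minute each.

## Known limitations

* The Welch-on-log2 significance stand-in is not the read-level test the
  original analyses used; absolute PM/PZ counts on real data will differ
  near the significance boundary.
* One rate pair per stage ignores rate heterogeneity across genes; a
  gamma mixture over rates would be the natural extension.
* The 90/90 rule on marginal posteriors can call at most one event per
  branch per character and cannot see multiple hits along a branch.
* Ortholog groups with multiple orthologs in a species are treated as
  unknown in that species, losing whatever signal the paralogs carry.
* The tree is an input and is taken as known without uncertainty.
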