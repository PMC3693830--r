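---
title: "Attributing drug side effects to protein targets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attributing drug side effects to protein targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adrtarget)
library(dplyr)
```

## The model

A drug is a perturbation experiment run in thousands of patients: it engages
a set of proteins (its targets and off-targets, sometimes with a known
agonist/antagonist action mode) and produces a set of phenotypes recorded as
side effects on its label. Neither observation alone identifies *which*
protein causes *which* side effect — but across hundreds of drugs the two
annotations can be crossed. The working assumption of this package is that a
causal protein leaves a reproducible statistical footprint: drugs that
perturb it elicit its side effect more often than the background incidence
of that side effect, independently of chemistry or indication.

For a target node $t$ and side effect $s$ we form the $2\times2$ table over
the non-redundant drug set — $a$ drugs binding $t$ and eliciting $s$, $b$
binding only, $c$ eliciting only, $d$ neither — and compute the one-sided
Fisher exact tail $P(X \ge a)$ with all margins fixed. One-sided, because
only overrepresentation is evidence of causation; underrepresentation has no
causal reading here (a two-sided variant is available via
`run_enrichment(alternative = "two.sided")`). The tail is evaluated through
the log-space hypergeometric distribution function, so p-values far below
double precision's comfortable range keep full relative accuracy; there is
no continuity correction.

Only pairs with $a \ge 1$ are tested. A pair never co-annotated on any drug
carries no information for overrepresentation, and including such pairs
would only dilute the multiple-testing correction; the tested universe is
therefore "pairs with at least one co-annotated drug", and q-values are
estimated jointly over exactly that universe.

### Action modes as virtual targets

Activating and inhibiting a receptor are different perturbations with
different phenotypes, so where a drug's action mode on a protein is known,
the edge is duplicated onto a virtual node: a beta blocker targets both
`ADRB1` (binding) and `ADRB1:inhibition`. Both node kinds are tested; in
benchmarks and reporting the variants of one protein are collapsed to the
best (smallest) q-value, since any variant being verified validates the
protein-level call. Virtual nodes also make mode-specific predictions
actionable: a side effect attributed to *activation* of a receptor suggests
blocking it.

### Redundancy on both sides of the network

Two redundancies would otherwise distort the counts:

* **Indistinguishable targets.** Proteins bound by exactly the same drugs
  (family members, complex subunits) cannot be separated by this data; they
  are merged into one node whose members are reported together. Merging is
  computed over the *active* (non-redundant) drug set, i.e. after drug
  de-redundancy — the merge criterion and the counting population should be
  the same.
* **Chemically redundant drugs.** Near-identical molecules are not
  independent experiments; they share targets and labels by construction.
  Drugs more similar than Tanimoto 0.7 (2D fingerprints) are reduced with
  Hobohm's algorithm 2: repeatedly delete the drug with the most
  above-cutoff neighbours until none remain. Ties are broken by removing the
  lexicographically greatest drug id, making the reduction deterministic
  without a seed; the no-similar-pair post-condition is asserted on every
  run. Drugs without fingerprints are kept (with a warning) — absence of
  chemistry is not evidence of redundancy. Removed drugs leave the *active*
  counting set only: they remain in the network and are still explained in
  the attribution stage, where every observed drug matters.

Targets and side effects associated with fewer than five active drugs are
removed before testing; below that support the exact test cannot reach
interesting significance and the pairs only pad the correction. Because
drugs are never removed by this filter, it is a single pass.

## False discovery control

q-values are computed with the Storey approach: the true-null proportion
$\pi_0$ is estimated from $\pi_0(\lambda) = \#\{p > \lambda\}/(m(1-\lambda))$
on the grid $\lambda = 0, 0.05, \dots, 0.90$, smoothed with a natural cubic
smoothing spline (df = 3) and read off at the largest $\lambda$; then
$q_i = \min_{p_j \ge p_i} \pi_0\, m\, p_j / \mathrm{rank}_j$, clipped to
$[0,1]$. With $\pi_0 = 1$ this is exactly Benjamini–Hochberg, and the
arithmetic deliberately mirrors `p.adjust(method = "BH")` so the two agree
bit-for-bit — a property the test suite asserts on a thousand random
p-vectors.

The smoother needs its own assumption checked. It reads $\pi_0$ off the tail
of the p-value distribution, presuming null p-values are uniform; any
mixture with a sizeable null fraction then puts roughly
$\pi_0 (1 - \lambda_{max})$ of its mass above $\lambda_{max}$. Discrete
one-sided Fisher p-values restricted to pairs with $a \ge 1$ violate this:
for small margins the attainable p-values stop well short of 1, the tail is
empty, and the spline extrapolates towards 0 — which would declare nearly
everything significant. `estimate_qvalues()` therefore falls back to the
conservative $\pi_0 = 1$ whenever fewer than 100 p-values are supplied, the
observed tail above $\lambda_{max}$ holds under a quarter of the uniform
expectation, or the smoothed estimate is non-positive. On the synthetic
worlds below the fallback engages routinely, so their q-values are
effectively BH-adjusted — conservative, never anti-conservative.

Predictions for metabolizing enzymes are flagged *after* testing rather than
dropped beforehand: their associations are real but indirect (shared
metabolites, altered exposure), so they are excluded from significance
counts, clustering and explanation while remaining visible in the output. A
merged node is flagged if any member is metabolizing.

## Co-binding clusters

Because drugs bind most members of a protein family, a causal family member
drags its siblings into significance. Counting each sibling as an
independent discovery would inflate both the discovery count and the false
positive rate, so per side effect the significant targets are clustered:
targets $t_1, t_2$ are linked when at least half of the drugs binding one
also bind the other. The criterion is directional; a link is created if
either direction reaches 0.5 ("at least half" is $\ge$), and clusters are
the connected components of the resulting graph — the minimal deterministic
closure of the pairwise rule. Components (single linkage) are used because
the intent is agglomeration around a known causal protein: when a cluster
contains known causal proteins, the one attached to the smallest q becomes
the cluster seed (others stay members and are logged). One consequence,
verified in the tests: with a threshold above 1 every cluster is a
singleton.

Clusters are the counting unit of verification — one verified member
explains the whole cluster.

## Benchmarking

Two complementary checks against an independent reference (literature pairs
or mouse-knockout phenotypes mapped to side-effect terms by strict synonym
matching; unmapped phenotypes are skipped and counted):

* **Distribution shift.** After collapsing to base proteins, reference pairs
  should have smaller q-values than the remaining tested pairs. The
  one-sided two-sample Kolmogorov–Smirnov statistic
  $D^+ = \sup_x [F_{ref}(x) - F_{bg}(x)]$ is tested by label permutation —
  exact enumeration of all $\binom{m+n}{m}$ splits when that is within the
  permutation budget (default $10^5$), random shuffles otherwise. The
  permutation p-value is primary because realistic reference sets hold a few
  dozen pairs, too few for asymptotics; the asymptotic bound
  $\exp(-2 D^{+2} mn/(m+n))$ is reported alongside and agrees within a small
  factor at moderate sample sizes. The permutation loop is compiled (Rcpp),
  as is usual for permutation tests, since the background can hold thousands
  of q-values.
* **Match-rate enrichment.** A cluster matches the reference if any member
  protein forms a reference pair with the cluster's side effect. Significant
  clusters are tested for match enrichment over all clusters (the same
  one-sided Fisher machinery) on the table (matched, unmatched) ×
  (significant, other). A pair-level variant (`unit = "pair"`) reproduces
  the no-clustering view. The background cluster total is taken to include
  the significant clusters, i.e. columns are "significant" and
  "non-significant" with the published-style margins.

## Attribution of observed drug–side-effect pairs

With causal predictions in hand, each observed drug–side-effect pair (over
the *full* drug set — chemical de-redundancy only concerned counting) is
explained by the significant causal nodes among that drug's own targets.
Mode compatibility is structural: a drug reaches `P:inhibition` only if it
is annotated to inhibit P, while generic binding nodes match any binder.
Node-level significance (q < 0.01) is required — clusters are not expanded,
so a drug must bind a significant node itself.

Main targets (the proteins credited with the therapeutic mechanism) are
resolved per drug, with whole-family annotations removed: candidates in a
family with 10 or more members within the drug's candidate list are dropped,
so a kinase inhibitor does not carry every kinase as a main target. Families
are assigned by the annotation term with the highest count, ties broken by
the fixed precedence GPCR > nuclear receptor > ion channel > kinase >
enzyme > other. Each explained pair is then categorised main-only / both /
off-only / unexplained (a partition, asserted in the tests), and fractions
are reported per protein family and per the drug's most prevalent
main-target family.

## The synthetic world generator

`simulate_world()` emulates the statistical structure the method relies on,
with known ground truth:

* 100 proteins in 20 families of 5; 300 drugs, each centred on one family
  (binding members with probability 0.8, everything else with 0.02) — the
  family-wise binding that motivates both target merging and clustering;
* action modes: each protein has a canonical pharmacology direction; an
  edge's mode is annotated with probability 0.8 and agrees with the
  canonical direction with probability 0.95. These reflect that curated
  mode annotations cover most (not all) edges and that drugs binding a given
  receptor overwhelmingly share their pharmacology;
* 50 side effects and 30 planted causal (protein, canonical mode, side
  effect) relations with penetrance 0.8, combined with a background
  eliciting rate of 0.05 by noisy-OR — the simplest generative rule in which
  any perturbed causal target or the background can independently trigger
  the phenotype;
* fingerprints of 256 bits: family prototypes mutated per drug at rate 0.2
  (in-family Tanimoto ≈ 0.5, below the 0.7 cutoff), plus 10 near-clone drugs
  mutated at 0.02 (Tanimoto ≈ 0.9, above it) that duplicate an existing
  drug's pharmacology — fodder for the Hobohm stage;
* a knockout reference containing each planted pair with sensitivity 0.8
  plus 30 uniform decoy pairs, and a complete phenotype→side-effect synonym
  map; half the planted pairs also enter the known-causal table used for
  cluster seeding; 5 non-causal proteins are flagged as metabolizing.

Everything is deterministic given the seed. What the generator does *not*
emulate: dose–response and exposure, correlated side effects, label
frequency classes, reporting biases, and the long-tailed degree
distributions of real pharmacology data. Passing recovery tests therefore
demonstrates that the machinery is correct and calibrated under the model's
own assumptions — not that real SIDER/STITCH-scale results are reproduced,
which require the proprietary snapshots.

At these defaults, averaged over ten seeds, cluster-level recall of planted
relations is ≈ 0.98 with empirical FDR ≈ 0.03 at q < 0.01, and on
background-only worlds (no planted pairs) essentially no pair is declared
significant — both recomputed by `scripts/acceptance.R` and asserted in the
test suite.

## Numerical and design notes

* Fisher tails come from the log-space hypergeometric CDF and match
  brute-force same-margin enumeration to 10⁻¹² for all tables with total
  ≤ 60 (asserted in the acceptance tests).
* Significance is a strict inequality (q < cutoff), so a record at exactly
  the cutoff is excluded.
* `select_significant()` and everything downstream ignore
  metabolizing-flagged records.
* Prediction tables serialize p and q at 17 significant digits, which
  round-trips IEEE doubles exactly.
* Cluster ids use `se:i`; `#` is reserved as the comment character of the
  TSV dialect.
* Side-effect frequency columns are read and preserved but unused by the
  statistics.
* The worked-example fixture (`worked_example_fixture()`) pads its 550-drug
  universe with inert targets so that every drug appears in at least one
  edge and the configuration survives a flat-file round trip; padding does
  not touch the (11, 1, 173, 365) table.
* Problem sizes in the test and acceptance runs (300-drug worlds, 10–20
  seeds, 2000–4000 permutations) were chosen as the smallest sizes at which
  the stochastic properties are stable; all scale linearly if increased.

## Known limitations

* Very common side effects with many independent causes are not resolvable:
  no single target is sufficiently overrepresented.
* Proteins bound by fewer than five drugs are untestable by design.
* The co-binding threshold (0.5) and Tanimoto cutoff (0.7) are the
  conventional values; the API exposes both, but no sensitivity analysis is
  built in.
* The π₀ smoother is conservative on strongly discrete p-value sets (see
  above); users wanting the classical smoother behaviour on continuous
  p-values get it automatically when the tail support exists.
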