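---
title: "Hybrid bioactivity-structure fingerprints: models, conventions, and the synthetic benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid bioactivity-structure fingerprints: models, conventions, and the synthetic benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The method

High-throughput screening (HTS) campaigns leave behind a large matrix of
compound-by-assay activity outcomes. Two families of descriptors are commonly
built from such data for virtual screening:

* the **HTS fingerprint (HTSFP)** — a binary vector per compound over a panel
  of historical assays, with bit = 1 where the compound was flagged active.
  It encodes bioactivity, not chemistry, which makes it a strong scaffold
  hopper but leaves it undefined for compounds without screening history and
  noisy for sparsely tested ones;
* the **extended-connectivity / Morgan circular fingerprint (ECFP4)** — a
  hashed binary encoding of circular atom environments up to radius 2 (the
  "4" is the diameter), folded to a fixed width. It encodes chemistry alone,
  so its predictions inherit the structural biases of the training actives
  and it is blind to activity cliffs.

This package implements the **bioactivity-structure hybrid (BaSH)**
fingerprint: the column-wise concatenation of the HTSFP block (first) and the
ECFP4 block (second). For a full-scale panel of 561 assays and a 1024-bit
ECFP4 the hybrid has width 1585. The hybrid's rationale is synergy: the
structural block "fortifies" compounds whose screening history is sparse, so
no HTSFP density cutoff is needed, while the bioactivity block contributes
target-level signal that no structural descriptor can carry.

Benchmarking is retrospective and leave-assay-out: for each test assay, its
own column is removed from the bioactivity block
(`exclude_assay()`), a random-forest classifier is trained per descriptor
under stratified six-fold cross-validation, and every compound receives a
held-out activity probability — the forest's consensus vote. Rankings,
confusion-based scores, enrichment factors, scaffold overlap, nearest-neighbor
similarity and cross-model rank scatter are all derived from those held-out
scores.

## Data conventions

Activity tables are delimited text with header
`assay_id,compound_id,outcome` (tab or comma, auto-detected). Outcomes other
than Active/Inactive (case-insensitive) — Inconclusive, Unspecified, Probe —
are mapped to an `other` category, which is treated as absent data: it is
discarded before replicate voting, and pairs observed only as `other` never
enter the panel. This is a package decision; screening depositions vary in
how they use non-binary flags, and counting them on either side of the vote
would fabricate information.

Replicate outcomes for the same compound-assay pair are resolved by majority
vote with exact ties going to *active* — the asymmetric rule reflects that a
rare active flag on a heavily imbalanced screen carries more information than
an inactive one. Resolution is idempotent, and the resolved flag equals the
rule "active iff #active ≥ #inactive" on any flag multiset (the test suite
checks this against brute-force enumeration).

In the HTSFP, resolved-inactive and never-tested both encode as 0. On panels
with sub-percent hit rates, an untested compound is overwhelmingly likely to
be inactive, so collapsing "missing" onto "inactive" trades a small false-bit
rate for a usable dense encoding; the test suite pins the consequence
(tested-inactive row == never-tested row) so the choice is explicit.

Structural fingerprints are computed from SMILES with OpenBabel's
extended-connectivity implementation and OR-folded from the native 4096 bits
to the configured width (1024 by default) by the standard modulo rule. Folded
bits are anonymous hash buckets: the package guarantees determinism and
invariance to the textual rendering of a molecule, not compatibility with any
other toolkit's bit numbering. Structure tables are validated on load;
unparsable SMILES are quarantined in a `rejected` slot and duplicated ids
keep their first structure.

## Random-forest configuration

The three shipped presets carry the published hyperparameter sets for the
descriptor types:

| preset | trees | criterion | max depth | min leaf |
|--------|------:|-----------|----------:|---------:|
| `htsfp` | 150 | entropy | 40 | 5 |
| `ecfp4` | 200 | gini | 30 | 8 |
| `bash` | 150 | gini | unlimited | 8 |

All use balanced class weighting (inverse-frequency case weights
`n/(2 n_c)`; indispensable at 0.05-4% prevalence), `sqrt(p)` candidate
features per split, and forest seed 56. Forests are grown with `ranger`.
Two engine mappings are worth stating plainly: `ranger` offers only the Gini
impurity for classification splits, so the `entropy` annotation of the HTSFP
preset is recorded in the configuration but honoured as Gini — on binary
features the two impurities select near-identical splits; and the
scikit-learn pair (`min_samples_split`, `min_samples_leaf`) maps onto
(`min.node.size`, `min.bucket`). Held-out probabilities are those of a
probability forest (averaged terminal-node class frequencies), the standard
forest consensus estimate.

The decision threshold for confusion-based metrics is 0.5 — the majority
vote of the trees. It is exposed in the configuration because the choice of
operating point on heavily imbalanced screens is a genuine free parameter;
threshold-free metrics (ROC-AUC, EF) do not depend on it. Stratified folds
are dealt round-robin from per-class shuffles under a dedicated fold seed
(default also 56), so per-fold class counts differ by at most one and the
assignment is a pure function of `(labels, k, seed)`. All randomness is
scoped: package functions never disturb the caller's RNG stream.

## Metric conventions

The evaluation suite implements the confusion-matrix rates, precision /
recall / F1, the Matthews correlation coefficient, Cohen's kappa, ROC-AUC by
trapezoidal integration over distinct-score thresholds (tied scores form one
step, which makes the AUC equal the normalized Mann-Whitney statistic), and
the enrichment factor

$$\mathrm{EF}_{x\%} = \frac{\mathrm{Hitrate}^{x\%}}{\mathrm{Hitrate}^{100\%}},$$

with selection size `floor(x N)`, minimum 1. Zero-denominator conventions
are explicit: MCC is 0 when a marginal is empty, precision/recall/F1 are 0
with a warning on degenerate folds, kappa is undefined at chance agreement 1,
and EF raises an error when the screen has no actives. Per-assay results are
reported as mean ± SD across the six folds (fold-wise aggregation, matching
how per-fold selections are made); EF columns are reported at 1, 1.5, 2 and
2.5%. Every metric is checked in the test suite against an independent
brute-force oracle on exhaustive small instances.

The top-scoring selection is computed in two modes, because both are useful:
per-fold top-x% (feeding the scaffold analysis, which averages over folds)
and pooled held-out top-N across folds (feeding the ranking comparison and
nearest-neighbor analysis). Ties in scores break deterministically by
ascending compound id.

## Scaffold and diversity analysis

The generic (topological) Bemis-Murcko scaffold is computed by iteratively
deleting terminal atoms until only ring systems and their linkers remain,
converting every remaining atom to carbon and every bond to a single bond,
and canonicalizing the resulting skeleton. Toluene and pyridine both reduce
to the C6 carbocycle; the transformation is idempotent. Acyclic molecules
have no framework and are excluded from scaffold counting — a "no scaffold"
pseudo-class would spuriously merge all acyclic actives into one identity.

Scaffold overlap between the three models' true-positive selections is
reported as the seven region counts of the three-set Venn diagram, computed
per fold and averaged (means are kept exact in the data structures and only
rounded for display). Nearest-neighbor Tanimoto similarity is always computed
on the *structural* fingerprint, whichever model produced the selection, so
the three distributions are comparable on one chemical axis.

## The synthetic world

Real panel data at full scale (hundreds of assays, ~7×10^5 compounds) is
not needed for any test: the generator builds worlds with the statistics that
matter for the pipeline, at desk scale.

* **Library**: each compound is one of up to ten ring-system templates
  (benzene, pyridine, naphthalene, piperidine, thiophene, furan, pyrimidine,
  indole, quinoline, tetralin) decorated with 1-2 substituents from a fixed
  25-fragment grammar. All generated SMILES are valid by construction (the
  suite verifies every template-substituent combination), and same-chemotype
  compounds are measurably closer in Tanimoto space than cross-chemotype
  ones.
* **Latent pharmacology**: a chemotype-by-target affinity matrix plus a
  per-compound idiosyncratic term give each compound a latent score per
  target. The idiosyncratic term is what makes bioactivity information
  genuinely complementary to structure: two compounds of the same chemotype
  can differ in latent activity — the generator's rendering of an activity
  cliff.
* **Panel**: each assay reads one latent target through a logistic link,
  with the intercept calibrated numerically (`uniroot`) so the realized hit
  rate among tested compounds matches a rate drawn uniformly from 0.05-4%.
  Compounds are tested with probability 0.35, so most cells are missing.
* **Test assay**: labels follow a latent-utility model — standardized
  chemotype effect times `structure_weight`, plus standardized latent-target
  score times `bioactivity_weight`, plus logistic noise — thresholded at the
  requested prevalence (2% by default), so the active count is exact.

Four generator constants deserve justification, because the first design we
tried transmitted almost no panel signal into the fingerprint bits and the
diagnosis is instructive. With a shallow logistic link of slope β, an assay's
actives concentrate around latent score z ≈ β; compounds that are merely
*moderately* elevated — which is where a mixed-signal test assay's actives
sit — are barely enriched, and the per-assay lift available to them is capped
at about e^(z²/2). A recoverable bioactivity channel therefore needs (i) a
**sharp link** (`link_slope = 6`): assays behave like thresholded readouts of
their target, the regime in which overlap between a test assay and its
sister assays is strong; (ii) **several sister assays**: 5 latent targets
behind 50 assays gives each target ~10 readouts, mirroring the
confirmatory/related-assay redundancy of real collections; (iii) **label
noise below the systematic effects** (`label_noise = 0.5`, logistic noise
with sd ≈ 0.9 against two unit-variance signals); and (iv) rates drawn
**uniformly** (mean 2%) rather than log-uniformly, since sub-0.1% assays
contribute almost no active bits at 5000 compounds. All four are ordinary
config fields; worlds with other regimes (structure-only, panel-only,
null-affinity) are one argument away and are used in the test suite to check
that model performance and feature-importance patterns follow the generating
regime.

What the generator does *not* emulate: frequent hitters and assay
interference (PAINS), correlated assay noise, batch effects, and realistic
chemical diversity — the finite template-substituent grammar produces
duplicate structures at desk scale, which compresses nearest-neighbor
similarity distributions toward 1. Conclusions from passing tests are about
the pipeline's correctness and the recoverability of designed signal, not
about expected performance on any real screen.

## Feature importance and what "block dominance" means

Per-fold Gini importances are normalized to sum to one, then averaged
per-feature across folds; block totals are sums of per-feature means within
the bioactivity and structural blocks. A practical caveat, visible in both
real and synthetic data: a thousand dense structural bits soak up a basal
level of impurity importance even when structure is uninformative, so block
*totals* understate the bioactivity contribution. The discriminating pattern
is pronounced individual features: when test-assay activity is driven by the
panel, the top-ranked features are sister-assay columns and the bioactivity
block total rises by an order of magnitude over structure-only worlds. The
test suite asserts exactly that pattern.

## Problem sizes and runtime

The shipped tests run the full pipeline on worlds of 600-2000 compounds and
15-40 assays, and the synergy benchmark on ten seeds at 5000 compounds and
50 panel assays — sizes chosen so the whole suite completes in minutes on a
single core while every fold still contains double-digit actives. The
acceptance script's null-enrichment calibration uses 100 screens of 200,000
compounds. At these scales the per-fold top-1% selection can be just a
handful of compounds, which makes fold-level EF and scaffold counts granular;
the workflow exposes the selection fraction so desk-scale analyses can widen
it.

## Known limitations

* OpenBabel's ECFP bit assignments differ from other toolkits'; models and
  analyses are internally consistent but folded-bit identities are not
  portable.
* The `entropy` split criterion is honoured as Gini (engine limitation;
  see above).
* Venn region means over folds are non-integers; display rounds them.
* The generator's compound universe contains duplicate structures by design
  of its small grammar; deduplicate by canonical SMILES if that matters for
  an analysis.
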