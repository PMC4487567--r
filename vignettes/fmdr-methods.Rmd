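---
title: "MDR and FMDR: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MDR and FMDR: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmdr)
```

## The model

Multifactor dimensionality reduction treats an order-n locus set
L = {l1, ..., ln} as a single constructed attribute.  Each observed
multi-locus genotype cell (up to 3^n of them for SNPs coded 0/1/2) is
assigned to a high-risk or low-risk pool by comparing its
imbalance-corrected case:control ratio

f(L) = (N* x cases-in-cell) / (P* x controls-in-cell)

against a threshold T, where P* and N* are the case and control totals of
the training set.  The correction term N*/P* is what keeps T = 1
meaningful when controls outnumber cases: a cell is "high risk" when its
case fraction exceeds the *cohort's own* baseline, not one half.  Cells at
exactly T are labelled H ("equal to or greater"); cells with cases but no
controls have an infinite ratio and are H; cells with controls but no
cases are L.  Pooling H against L cells reduces the n-SNP predictor to one
binary attribute whose 2x2 confusion table is scored by the balanced
classification error 0.5 (FN/(TP+FN) + FP/(FP+TN)) — 0 is perfect, 0.5 is
chance, and the statistic is invariant to duplicating every sample.

The analysis layer is V-fold cross-validation (V = 10 by default).
Samples are shuffled by a seeded RNG and dealt into V near-equal blocks
*without* class stratification; the training-set control:case ratio
therefore varies from fold to fold around the cohort ratio, which is the
behaviour of randomly sorted data sets and is deliberately preserved (a
stratified split would be "better practice" but a different procedure).
Per fold, the search minimises training error; the fold-best model of each
order is then scored once on the held-out tenth *using the training
labelling*.  Test samples falling in cells never observed during training
carry no evidence and are conservatively assigned L.  Across folds the
final model per order is the one appearing most often among fold bests
(cross-validation consistency, reported "k / V"); ties are broken by lower
mean testing error, then by lexicographically smallest locus tuple, so the
selection is deterministic.  Reported accuracy is 1 minus the unweighted
mean of the V fold-best testing errors — an average over models, not over
samples.  Whether such a table's "accuracy" means training or testing
accuracy is ambiguous in parts of the MDR literature; this package always
reports testing accuracy.

## The greedy search

FMDR rests on the joint-effect property: a genuine n-locus epistatic
model tends to leave a detectable (n-1)-locus sub-signal.  Order 2 is
seeded exhaustively (all C(N,2) pairs).  After ranking, each fold keeps
the best n% of the candidates it just evaluated in its own fold memory —
retention is strictly per fold, with no cross-fold pooling — and order
m+1 candidates are generated only by extending each retained combination
with every SNP not already in it, collapsing duplicates to their sorted
canonical form.  Cost per order is therefore at most |retained| x N
instead of C(N, m), and the per-order evaluated counts are recorded in
the fit's `accounting` field so the saving is auditable rather than
asserted.

Two readings of "keep the best n" circulate: a percentage of candidates,
or a bare count ("top 2 at order 2, top 3 at order 3").  The percentage
reading is the default here because it is well defined at every order:
retained = max(min_retained, ceiling(pct/100 x evaluated)), capped at the
number evaluated.  The count reading remains available through the
per-order override map and `min_retained`.  Only the fold-best model is
rescored on the held-out tenth; retained non-best models exist solely to
seed the next order.

Two properties anchor correctness.  With retain = 100% the greedy search
evaluates exactly the exhaustive candidate set at every order, so FMDR
must reproduce MDR bit for bit (same folds, same seed) — the test suite
asserts this over 20 seeds at orders 2–4.  And because greedy retention
can only discard candidates, FMDR's best training error at any order is
never below MDR's, while its evaluated-combination count is never above
C(N,m) x V, strictly below it for m > 2 at partial retention.

## Tunable parameters

* `retain` (default 10, percent): the only FMDR-specific knob.  Smaller is
  faster and greedier; 100 recovers exhaustive MDR.  10% keeps the search
  cost near |retained| x N while leaving, at typical SNP-panel sizes,
  dozens of parent combinations per fold — enough that a true pair's
  sub-signal rarely falls off the list.
* `threshold` (T, default 1): the H/L ratio boundary.  With the N*/P*
  correction in place 1 is the natural prior-free choice; it is exposed
  because threshold-shifted variants are common in practice.
* `folds` (default 10): classical ten-fold cross-validation.
* `min_retained` (default 1): floor on the memory size, guaranteeing the
  greedy loop can always advance.
* `seed`: controls only the fold shuffle (and, in the simulator, the
  draws); the search itself is deterministic, so a fit is exactly
  reproducible from (data, method, parameters, seed).

## The simulator

`sample_penetrance_model()` draws random n-locus penetrance architectures
at a target broad-sense heritability h2 = sum p_g (f_g - K)^2 / (K(1-K))
under per-locus Hardy–Weinberg genotype frequencies, where K is the
prevalence implied by the table.  A draw from Uniform(0,1) per cell is
alternately (a) flattened — each locus's marginal penetrance deviation
from K is subtracted, removing main effects — and (b) rescaled about K to
hit the target h2, then clipped to [0,1]; draws that fail either
invariant (realised h2 within 10% relative of target, per-locus marginal
deviation under 0.01 on the penetrance scale) are rejected and redrawn.
The 0.01 purity tolerance is tight enough that single-locus association
tests on the causal loci stay null at the sample sizes used here, which
is what "pure epistasis" has to mean operationally.  No attempt is made
to reproduce any particular architecture-sampling algorithm: the
benchmark architectures in this literature are themselves random and
unpublished, so the invariants, not the values, are the specification.
Prevalence is left wherever the accepted draw lands unless `K_target` is
supplied — case/control sampling conditions on phenotype, so K affects
only sampling efficiency, not the data distribution given class.

`generate_dataset()` fills exact case and control quotas by rejection:
causal genotypes are drawn from their HWE joint distribution, case status
with probability equal to the cell penetrance.  Noise SNPs are i.i.d.
Hardy–Weinberg draws at `noise_maf` (defaulting to the causal MAF, so
noise loci are not distinguishable by allele frequency alone), and the
causal columns are hidden at seeded random positions.  The six standard
benchmark designs (`simulation_designs()`) cross MAF 0.1/0.2/0.4 with
balanced sample sizes 800/1600 at h2 = 0.2 and 50 SNPs.

What the simulator does *not* emulate: linkage disequilibrium between
SNPs, missing genotypes, covariates, quantitative traits, and
population structure.  Passing power tests on these data therefore show
that the search machinery works when the signal is a clean pure
interaction among independent loci — they do not certify performance on
real cohorts, where LD can smear a signal across neighbours and missing
data must be handled upstream (this package rejects it loudly rather
than imputing).

## Numerical and degenerate-input choices

* Empty-control cells are H, empty-case cells are L, unobserved cells are
  unlabelled; test samples in unlabelled cells count as L (TN/FN).
* `cell_ratio()` returns `Inf` for case-only cells and `NA` for empty
  cells; observed-cell labelling never sees the `NA` case.
* A fold whose training or test part lacks one class is an error advising
  a reshuffle with a new seed rather than a silent skip.
* Odds ratios use the Woolf log-normal interval
  exp(ln OR ± z sqrt(1/TP + 1/FP + 1/TN + 1/FN)); zero cells require the
  explicit Haldane–Anscombe +0.5 flag.  The whole-data OR printed by
  `summary()` uses that correction since final models often have
  case-only cells.
* Paired t-tests with zero-variance differences are flagged degenerate
  (printed "-"), the convention for identical method results.
* Power is exact recovery: the final selected model must equal the
  planted causal set (no credit for supersets); its SD is the sample SD
  of the per-replicate 0/1 indicator.

## Problem sizes used in the shipped checks

The package's own test suite runs the fold-ratio study at the cohort
shape 193 cases / 704 controls (100 sorts x 10 folds), the
greedy/exhaustive equivalence on 8–10-SNP fixtures at orders 2–4 over 20
seeds, and the power study at 2 causal loci, MAF 0.2, h2 0.2 and 0.4,
800 + 800 samples, 20 SNPs, 50 replicates per arm — sizes chosen so the
whole suite completes in a few minutes on one core while still putting
every claim (equivalence, accounting, recovery) through a non-trivial
instance.  Larger sweeps are a matter of turning the same knobs.

## Known limitations

Exhaustive MDR beyond order ~5 on dense panels is out of reach by design
(that is the problem the greedy search addresses); the greedy search is a
heuristic and can lose an interaction whose sub-signals all rank below
the retention cut, a risk that grows as `retain` shrinks; and the method
is confined to complete-data, binary-phenotype, unlinked-SNP settings —
entropy-based interpretation, permutation significance testing,
covariate adjustment and missing-data handling are explicitly outside
scope.
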