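---
title: "Detecting somatic lncRNA mutations that unbalance ceRNA regulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting somatic lncRNA mutations that unbalance ceRNA regulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smilm)
```

## The problem and the model

Long non-coding RNAs participate in competing endogenous RNA (ceRNA)
regulation: a lncRNA (here called the **ceL**) and an mRNA (the **ceM**)
that share binding sites for the same miRNA compete for that miRNA, so
their expression levels are coupled with opposite sign through the
shared pool. A somatic mutation inside a miRNA response element (MRE)
of the lncRNA can create, strengthen, destroy or weaken the site, and
the imbalance propagates: more miRNA captured by the lncRNA means less
repression of the mRNA, and vice versa.

`smilm` implements this chain of reasoning as a testable pipeline. The
minimal analysis object is the **SMILM unit** — one somatic mutation,
one miRNA, the mutated lncRNA (ceL) and one experimentally validated
target mRNA of that miRNA (ceM). The pipeline (a) finds candidate MRE
changes from sequence, (b) classifies them into four affinity-change
states, (c) tests whether expression data support the predicted
direction of regulation, and (d) relates the affected ceMs to gene-set
membership and patient survival.

## Sequence windows

For each mutation mapped into spliced transcript coordinates we extract
a **control** window of 7 nt on either side of the mutated span and a
**mutant** window with the edit applied. The seed/context scorer
additionally receives an **extended** window padded upstream to 14 nt,
because seed-match scoring needs more 5' sequence context than the
alignment scorer. Windows are truncated (and flagged) at transcript
ends. Windows crossing exon–exon junctions use the spliced sequence —
the mature transcript is what the miRNA encounters — and alleles are
reverse-complemented onto the transcript strand.

## The two predictors

The pipeline scores both windows for every miRNA with two built-in
predictors that reproduce the threshold semantics of the standard
alignment-based and seed/context-based target-prediction tools. They
are transparent approximations, not wrappers: the pass thresholds are
the conventional strict cut-offs (alignment score > 160, duplex energy
< −20 kcal/mol, context score < −0.4), while the scoring internals are
deliberately simple, documented and fully testable. An import adapter
(`import_external_predictions()`) accepts tabular output of the real
tools keyed by (mutation, window, miRNA) and applies identical
thresholds, so real predictions can replace the built-ins without
touching the rest of the pipeline.

**Alignment scorer.** A Smith–Waterman local alignment of the reversed
miRNA against the window on a complementarity substitution matrix
(Watson–Crick +5, G:U wobble +1, mismatch −3, affine gaps −9/−4).
Substitution scores at miRNA seed positions 2–8 are multiplied by 4, so
a perfect complement of miRNA bases 1–15 scores 7·5·4 + 8·5 = 180.
Duplex energy is a per-pair sum (G:C −3, A:U −2, G:U −1 kcal/mol, +0.5
per gap run) — an intentionally simple stand-in for nearest-neighbour
thermodynamics; the synthetic generator plants duplexes that clear the
−20 threshold comfortably, so the simplification does not interact
with the statistics downstream. Ties are broken deterministically
(highest score, then leftmost window end, then 5'-most miRNA end, with
diagonal moves preferred in the traceback). The implementation is
checked cell-for-cell against an independent matched-pair-chain
enumeration oracle, which is itself validated against full recursive
enumeration on tiny cases.

**Seed/context scorer.** Canonical seed types (6mer, 7mer-A1, 7mer-m8,
8mer) are detected exactly; the context-style score adds to a
seed-type baseline (−0.03/−0.10/−0.16/−0.31) an AU-content term
(−0.25 × AU fraction of the up-to-10 flanking bases) and a 3'
supplementary-pairing term (−0.02 per base of the longest complement
run of miRNA positions 13–17 upstream of the site). The score is
monotone in seed strength at fixed flanks, which the tests assert.

A site is **present** when both predictors pass (`combine_rule =
"both"`). We read "identified by both tools" as an intersection — the
stricter and more reproducible choice — and expose `"either"` as a
configuration escape hatch.

## Affinity states and functional scores

Comparing control and mutant windows yields one of four states: site
**gain** (+1), **loss** (−1), **up** (+0.5, present in both windows
and strengthened), **down** (−0.5, weakened). Direction for up/down
requires a margin — at least 1 alignment unit, or 0.01 context units
when the alignment change is sub-threshold — because floating-point
equal scores must not be called directional. The margin is our
quantitative choice; no published value exists for how much score
change separates "up/down" from no change. The **functional score** of
a mutation is the sum of its state scores over all affected miRNAs;
its sign predicts the net direction of miRNA capture by the lncRNA.
When a mutation hits several transcripts of one gene with conflicting
states, the transcript with the larger absolute alignment change wins;
exact ties are discarded and logged.

## High-frequency branch: bivariate genotype regression

Mutation sites carried by ≥ 2 samples of a cancer type are
**high-frequency (HF)**; the remainder are **low-frequency (LF)**. For
each HF unit we fit the two-response linear model

$$(E_l, E_m) = \mu + \eta\,Gt + \gamma\,MIr + \varepsilon,
  \qquad \varepsilon \sim \mathcal{N}_2(0, \Sigma)$$

on log2(FPKM+1) expression, with `Gt` the 0/1 carrier genotype and
`MIr` the miRNA expression covariate. Design choices:

* **Log transform.** FPKM is strongly heteroscedastic; log2(FPKM+1) is
  the standard variance-stabilising choice and is configurable off.
* **Joint test.** "p < 0.05" is read as the Pillai-trace test of the
  genotype term across both responses, with the term ordered last so
  it is adjusted for the miRNA covariate; per-response t-tests are
  reported alongside for transparency.
* **Covariate handling.** The miRNA enters as an ordinary covariate
  (adjustment by inclusion), not by pre-residualising the responses.
* **No multiplicity correction by default** — the filter is a raw 0.05
  screen; a Benjamini–Hochberg flag is available downstream for the
  enrichment tables.

Units pass **step 1** when the genotype effects on ceL and ceM are
opposite-signed and jointly significant (η_l × η_m < 0, p < 0.05), and
**step 2** when the ceL effect direction is consistent with the
predicted binding change: a net gain of miRNA binding on the lncRNA
(positive functional score) should lower ceL expression in carriers
and raise the ceM, so we require sign(η_l) = −sign(functional score).
Units with functional score 0 have no defined direction and are
excluded with a reason code.

**Degenerate fits.** With zero residual variance (an exact fit, e.g.
noiseless synthetic data) the test statistics are undefined; we adopt
the convention p = 0 for a nonzero coefficient and p = 1 otherwise,
with coefficients below 1e-10 snapped to zero so that sign filters
cannot be driven by rounding noise.

**Calibration note.** The size of the joint test is the meaningful
type-I-error quantity, and it is what the calibration tests check
(rejection rate within [0.03, 0.07] at α = 0.05 over 2000 null units).
The full step-1 rate under an exchangeable null is ≈ half that, since
the sign-product condition holds with probability ≈ 1/2 given
rejection — a direction constraint, not a significance test.

## Low-frequency branch: grouped t-tests

LF units are grouped per (ceM, cancer): samples carrying any LF
mutation that perturbs the ceM versus all other samples with
expression data. The test is the classic pooled-variance Student
t-test on log2(FPKM+1) (a Welch flag exists for the often extreme
group imbalance, default off, matching the named test). Fold change is
reported on raw FPKM group means with a 0.01 pseudo-count, so
identical groups give exactly 1. Groups need ≥ 2 mutated and ≥ 2
control samples (a variance needs two observations); smaller groups
are reported in an audit table rather than silently dropped. Each ceM
is annotated with its predicted **tendency** — the sign of the summed
mutation scores over its units (up / down / none). Tests are always
per cancer type, never pooled.

## Enrichment and survival

Over-representation uses the exact hypergeometric upper tail with BH
adjustment; the universe is all genes present in that cancer's
expression matrix (the natural background for expression-derived gene
lists). Rank-based enrichment uses the weighted Kolmogorov–Smirnov
running sum over genes ranked by signed log2 fold change, with
gene-label permutation (seeded, 1000 permutations by default) — the
permutation scheme available without per-sample phenotype
recomputation.

For survival, each sample is classed per ceM as **None** (no
perturbing mutation), **Up-regulated** (only positive-score
mutations), **Down-regulated** (only negative) or **Unknown** (both
directions present). Two complementary analyses follow: a
single-covariate Cox proportional-hazards fit on continuous
log2(FPKM+1) ceM expression (Efron tie handling, the common default;
HR < 1 with p < 0.05 flags association with reduced risk), and
Kaplan–Meier curves with a multi-group log-rank test across the
classes, merging classes below 3 samples into "other". Survival time
is taken in days as given; no administrative censoring is imposed on
real inputs.

## The synthetic generator

`simulate_bundle()` emits every input the pipeline consumes — genome
FASTA, GTF, mature miRNAs, validated interactions, per-sample
mutations, three FPKM matrices, clinical follow-up, gene sets — with
known ground truth, all driven by one seed (identical seed, identical
bundle, byte-for-byte on disk).

**Site geometry.** Planted MREs are built as
`supplementary(m9–m16) + m8-pair + 6mer + A1` in target space. This
layout is forced by the window geometry: with ±7 nt windows and the
both-predictors rule, *gain/loss* mutations must sit at the m8-pairing
base (the only seed-adjacent position whose ±7 window still covers the
full seed plus enough supplementary pairing to clear the 160
threshold), and *up/down* mutations must sit in the supplementary
region at the m9-pairing base, toggling A↔T so the AU-flank term of
the context score is unchanged while the alignment score moves by ±8.
Planted miRNAs fix position 1 and 9 to U and keep positions 10–13 A/U
so flanks stay AU-rich and the context threshold is cleared by
construction. The generator *verifies* every planted state by running
the actual predictors and classifier at build time, resampling flanks
on collision.

**Expression.** Generated on the log2 scale as
`E = μ + η·Gt + loading·(MIr − mean) + ε` and stored as FPKM via
`2^E − 1` (floored at 0), so the pipeline's log2(FPKM+1) transform
recovers the planted linear model exactly up to the floor. Defaults —
one 60-sample cohort, 20 carriers per HF mutation, planted
(η_l, η_m) = (∓2, ±1) with sign tied to the planted state, noise σ = 1,
two LF ceMs with five single-carrier mutations and a 1.5 log2-unit
shift, survival log-hazard 0.7 on the planted up-regulated class —
are the conditions used throughout the validation suite; baselines
μ ∈ [5, 7] keep FPKM well away from the floor. The miRNA spread has
its own parameter (`mir_sigma`) because the miRNA is a covariate, not
noise: a noiseless (σ = 0) bundle must still have a non-degenerate
design matrix.

**What it does not emulate:** realistic mutational signatures,
genome-scale sequence, secondary-structure accessibility, correlated
expression networks beyond the planted units, copy-number or
methylation confounders, non-exponential hazards. Passing tests on
these bundles demonstrates that the *inference machinery* is correct
and calibrated, not that the biological error rates on real tumour
data equal the nominal ones.

## Validation design and problem sizes

The test suite validates each numerical core against an independent
oracle: the aligner against matched-pair-chain enumeration (itself
checked by full recursion on tiny cases), the regression against
explicit normal equations with an SSCP-based Pillai test, ORA against
exact combinatorial enumeration. Calibration uses 2000 null
replicates per branch (joint test, LF t-test, log-rank), recovery 500
replicates of the 60-sample/20-carrier regression design and 200
replicates of a 200-sample Cox design; the end-to-end round trip runs
the full pipeline on a noiseless bundle and requires exact recovery of
every planted unit with zero false positives. These sizes keep the
default suite under two minutes of statistical simulation while
leaving Monte-Carlo error well below the tested margins.

## Known limitations

* With noise, the joint genotype test is often driven by the ceL
  response alone, so other targets of the same miRNA ("bystander"
  ceMs with no true expression effect) can pass both filters about
  half the time their sign happens to match — visible in the
  stage-4 analysis output. This is a property of the published filter
  design, faithfully reproduced, and is why the noiseless round trip
  (where such units fail exactly) is the correctness criterion.
* The affinity margin (1 alignment unit / 0.01 context units) is a
  package choice; results near the margin are sensitive to it.
* The energy model is a per-pair sum; absolute energies are not
  comparable to thermodynamic predictions, only the thresholded
  decisions are meaningful.
* A single competing unit is modelled; network-level cascade effects
  of miRNA redistribution are out of scope.
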