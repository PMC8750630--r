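---
title: "Methods: HCC tumor-antigen discovery analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: HCC tumor-antigen discovery analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hccantigens)
```

# The problem

Hepatocellular carcinoma has few validated molecular targets. A
tumor-associated antigen (TAA) useful for vaccines or adoptive T-cell
therapy must satisfy several constraints at once: absent from normal liver
and other normal tissues (so therapy spares them), present in tumors of
many patients, prognostically meaningful, and a source of peptides that
HLA class I molecules present stably. A further, exploitable property is
*molecular mimicry*: if a tumor epitope closely resembles a viral epitope,
memory CD8+ T cells primed by past infection may cross-react with the
tumor. This package implements that discovery chain — cascade, survival
prioritization, epitope selection, mimicry scan, assay quantification —
as composable, tested R functions, with synthetic generators for every
input so the whole pipeline runs offline.

# The selection cascade

`run_cascade()` applies five filters in fixed order over two
immunohistochemistry (IHC) tables: a *normal-tissue* table (gene × tissue
× cell type, categorical level Not detected / Low / Medium / High) and a
*pathology* table (gene × cancer, patient counts per level, optional
prognostic annotation).

1. `stage_liver_negative`: keep genes whose liver records for hepatocytes
   and bile duct cells are all *Not detected*. Genes with no liver
   measurement are **excluded** and reported separately: absence of
   evidence is not evidence of absence. (This was a genuinely open design
   point; the permissive alternative would silently promote unmeasured
   genes.)
2. `stage_tumor_expressed`: keep genes with ≥ 1 liver-cancer sample at
   High, Medium or Low. The alternative reading — requiring a *fraction*
   of patients — is not adopted; a single detected sample suffices.
3. `stage_high_multi_sample`: keep genes with `n_high >= 2`, the strict
   reading of "high expression in more than one sample"; `min_high` is
   configurable.
4. `stage_pan_normal_negative`: keep genes with no non-liver normal
   record above *Not detected*, at any reliability grade by default. An
   optional `min_reliability` restricts the evidence to records at
   Enhanced/Supported/Approved, since IHC reliability annotation is
   heterogeneous; the default is the conservative all-grades check.
5. `stage_prognostic`: keep genes with best-expression-cutoff p strictly
   below `alpha = 0.05` **and** direction `"unfavorable"`. Favorable
   prognostic significance never passes — the target profile is "high
   expression, worse outcome".

Stages are intersected sequentially, so survivor sets are nested and
counts non-increasing by construction; the result object records per-stage
survivors, counts, and the genes dropped at each stage. The absolute
counts published for any given protein-atlas release are release-dependent
and are treated as audit fields, never assertions.

# Survival prioritization

`km_survival()` and `logrank_test()` wrap the product-limit estimator and
the two-group log-rank test from the `survival` package (standard
life-table tie convention: deaths before censorings at equal times).
`best_cutoff_scan()` reproduces the "best expression cutoff" semantics of
pathology-atlas prognostics: candidate cutoffs are the expression
quantiles 20%–80% in 5% steps (configurable), the cohort is dichotomized
at each (`>= cutoff` = high), and the reported p-score is the minimum
log-rank p across the grid, with the lower cutoff winning ties.

Deliberately, **no multiple-testing correction** is applied across the
scan — that matches the score's definition — so under the null the
minimum-p is anti-conservative. The test suite quantifies this: at
n = 100 with the default 13-point grid, the fraction of null cohorts with
best-p < 0.05 is well above the nominal 5% but below 40%. Users should
read p-scores as a ranking device, not calibrated error rates.

The 5-year readout (`five_year_delta()`) reports
100·(S_low(5) − S_high(5)) in percentage points; "unfavorable" means the
high-expression group survives less. Times are in years throughout; the
5-year horizon is a reporting-layer constant, configurable via `t`.

# Expression comparison

`paired_compare()` (paired two-sided t-test, for matched tumor/adjacent
tissue) and `unpaired_compare()` (Welch form, for unmatched public
cohorts) operate on a genes × samples matrix with tumor/normal labels and
an optional pairing bijection. A `log2(x + 1)` transform is on by default:
the expected input is count-scale RNA-seq abundance, where fold-changes
are the natural effect scale and the pseudo-count keeps zeros finite.
Strictly, the pseudo-count breaks exact scale invariance; for abundances
well above 1 the paired test is scale-invariant to numerical accuracy,
which the suite checks with an explicit tolerance. The Welch (unequal
variance) form was chosen for the unpaired test because public tumor and
normal cohorts differ in size and dispersion. `significance_stars()` uses
the conventional mapping (\*, \*\*, \*\*\*, \*\*\*\* at 0.05, 0.01, 0.001,
0.0001); a figure-legend variant that swaps the first two thresholds was
judged typographical and is not reproduced.

# Epitope selection

`enumerate_nonamers()` slides a 9-residue window one position at a time,
giving exactly L − 8 windows — nonamers being the canonical HLA class I
ligand length. Affinity bins are `lt10`, `10to50`, `50to100`, `gt100`
(nM), left-closed at 10 and 50: the published phrasing uses strict
inequalities on both sides of each boundary, leaving the boundary values
undefined, so a half-open convention was fixed and documented.
`select_strong_binders()` requires predictor class SB **and** affinity
strictly below 100 nM (the threshold below which predicted binders have
been observed to bind T2 cells ex vivo with full concordance);
`combine_stability()` additionally requires stability-class SB on the
(peptide, allele) join, optionally with a minimum Thalf in hours.
Predicted alleles default to HLA-A\*02:01 and HLA-A\*24:02; arbitrary
allele strings are accepted.

The neural-network predictors themselves are out of scope: real runs are
parsed from tool output files (`read_predictor_output()`, with
NetMHCpan-4.1-style, NetMHCstabpan-1.0-style and plain TSV dialects).
`toy_predictor()` is a deterministic stand-in for synthetic pipelines: a
position-weight score over anchor positions 2 and 9 (Leu/Met at p2 and
Val/Leu at p9 for A\*02-like alleles; aromatic anchors for A\*24-like)
plus a seeded integer-hash perturbation, mapped monotonically to affinity
(log10 scale 3.8 − 3.4·anchor + 0.4·u) and classed SB below 50 nM, WB
below 500 nM. The anchor term dominates the perturbation, so
anchor-optimal peptides always outrank anchor-broken ones. It is **not a
scientific predictor**; it exists so that planted "strong" peptides are
selected deterministically.

# Mimicry scan

`identity_score()` counts position-wise identical residues between two
9-mers; the ambiguity code X never matches anything, including another X.
`scan_viral_proteome()` compares *every* 9-mer window of *every* viral
record against every candidate epitope and keeps windows at
`min_identity >= 7` (the weakest retained homology grade in practice).
This replaces a heuristic BLAST search deliberately: retained pairs are
defined by exact position-wise identity, which BLAST only approximates,
and at desk scale (≤ 10⁷ residues) the exhaustive O(N·L) scan runs in
seconds. The implementation vectorizes over windows per record; its
defining correctness property — exact equality with an independently
coded naive double loop — is asserted over hundreds of randomized
instances in the suite. `filter_viral_binders()` then annotates viral
peptides with predicted affinity/stability and keeps classes {SB, WB}
with Thalf > 3 h: weak binders are admitted by default because validated
published pairs include WB-class viral peptides.

One published pair deserves a note: the ISG15-derived MLAGNEFQV and the
calicivirus-derived MLAGNAFTA are described as sharing 7/9 residues, but
position-wise comparison of the printed sequences gives 6/9 (mismatches
at positions 6, 8, 9). The package reports the computed value; the test
suite documents the discrepancy rather than reproducing the printed 7.

# Assay quantification

*T2 binding.* `fluorescence_index()` implements
FI = (MFI_sample − MFI_background)/MFI_background, scale-invariant by
construction; the binder call is FI > 0.5, strict, per the printed
threshold. `binding_profile()` reports FI per concentration (defaults 5,
10, 20, 50, 100 µM), an any-concentration binder call and a dose
monotonicity flag. Replicate MFI matrices (triplicate by default) are
averaged before FI, with SEM carried alongside.

*BFA decay.* `percent_remaining()` normalizes each timepoint (defaults
T0–T8, every 2 h) to 100 × MFI(t)/MFI(0). `dc50()` defaults to
**discrete** mode — the first sampled timepoint at ≤ 50% — because
dissociation readouts are reported as sampled timepoints ("reached at
T4"); interpolated mode (linear crossing between bracketing samples) is
provided for smoother synthetic work and is never later than the discrete
value when both exist. When 50% is never reached the result is an explicit
not-reached state printed as "> max h", not a number.

*Multimers.* `multimer_frequencies()` gates on live ∧ CD3⁺ ∧ CD8⁺ with
explicit per-channel thresholds — no automated gate inference, since the
gating strategy beyond live/CD3/CD8 is typically unspecified in published
work — and reports each multimer channel as a percentage of gated events.
Cross-reactivity per TAA–viral pair is operationalized as *double
positivity in both channels within the same event*; the alternative
(sequential single-multimer comparison) is noted but not implemented, and
the choice is visible in the configuration. `group_summary()` averages
per-donor percentages within donor groups.

# Synthetic data: what it emulates, and what it does not

The generators define the package's study conditions:

- `gen_hpa_tables()` emits a normal-tissue/pathology table pair with
  planted cascade positives (passing all five stages by construction) and
  distractors that each fail exactly one named stage, so every filter is
  exercised. Defaults: 100 genes, 9 planted positives, 12 IHC patients
  per gene, a five-tissue roster including the liver target cells.
- `gen_survival_cohort()` draws exponential event times at
  λ = −ln(S₅)/5 per group so each group's 5-year survival matches its
  target in expectation; defaults 28%/53%, the widest published
  high/low split. Expression is drawn at mean 3 (high) vs 1 (low),
  SD 0.25, so the planted cutoff is 2. Censoring is off by default
  (making Kaplan–Meier equal the empirical fraction, hence tight tests);
  a uniform-censoring variant exists.
- `gen_proteomes()` builds i.i.d. uniform-alphabet proteins (uniform
  residue frequencies rather than database-weighted: this keeps the
  mimicry false-positive rate exactly analyzable) with planted
  anchor-strong epitopes and viral homologs realized at exactly the
  requested identity via targeted mutation; verbatim published sequences
  can be planted directly.
- `gen_assay_data()` produces binding series from a saturating
  dose-response, decay series from exponential kinetics (default
  half-lives 4 h, 4 h and 24 h for the three pairs — the last one never
  reaching 50% within 8 h), and multimer event tables as mixtures of
  background and clone populations. Channel intensities are log-normal
  (CV ≈ 25%) with positive and background populations separated by far
  more than 5 CV, so threshold gating at the geometric midpoint is
  unambiguous. Default HCC-group frequencies are the published group
  averages (TAA 0.88/0.55/0.32%, viral 0.46/0.16/0.16%, cross
  0.298/0.11/0.04%); healthy-donor levels are not published and default
  to a 0.1% background with 0.02% cross.

What passing tests on these data *do* show: the pipeline's logic,
thresholds, joins and estimators are correct, calibrated and
deterministic under seed control. What they do *not* show: robustness to
real-data pathologies — IHC inter-observer noise, batch effects in
expression matrices, biased amino-acid composition, spectral spillover in
flow channels, or predictor error relative to experimental binding. Real
analyses should treat the synthetic results as verification, not
validation.

# Numerical choices and problem sizes

- Ties in the cutoff scan resolve to the lower cutoff; ties in event
  times follow the life-table convention inside `survival`.
- Degenerate inputs fail loudly: constant expression in a scan, empty
  gate denominators, non-positive backgrounds, sub-9-mer peptides.
- Determinism: every generator takes a mandatory seed and restores the
  caller's RNG state; the toy predictor uses exact 32-bit-range integer
  hashing in doubles, stable across platforms.
- Simulation sizes in the suite were chosen to make each check sharp yet
  quick: 1000-rep null for the log-rank and Welch type-I rates, 300-rep
  null for the cutoff-scan inflation bound, 200 randomized
  oracle-equality instances for the mimicry scan, 4 × 100,000 gated
  events for multimer recovery, and 25 replicate cohorts of 500/group
  for the survival-delta recovery (the Monte-Carlo SE of a single such
  cohort's delta is ≈ 3 pp, so recovery is asserted on the replicate
  mean, SE ≈ 0.6 pp, with a 3σ band per cohort).

# Known limitations

- The cascade operates on categorical IHC calls; it cannot recover
  quantitative dose effects within a level.
- The best-cutoff p-score is anti-conservative by design (see above) and
  the scan grid of any external pathology portal may differ from ours, so
  portal p-scores and ours need not match numerically.
- The mimicry scan is ungapped and length-locked at 9; insertions,
  deletions or register shifts between tumor and viral peptides are out
  of scope, as are E-value statistics.
- The toy predictor's SB/WB calls are arbitrary-but-consistent; nothing
  downstream should be interpreted biologically when it is in use.
- Cross-reactivity assumes combinatorial double staining; data produced
  by sequential single-multimer protocols would need the alternative
  definition.
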