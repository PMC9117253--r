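---
title: "Quantifying ubiquitinome dynamics with ubidyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ubiquitinome dynamics with ubidyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ubidyn)
```

## The analysis problem

Site-specific ubiquitination is measured by mass spectrometry through the
diGly remnant that tryptic digestion leaves on a modified lysine. A typical
experiment treats cells with inhibitors of the ubiquitin-proteasome system —
an E1 inhibitor such as TAK243, a proteasome inhibitor such as MG132, a
broad cysteine-DUB inhibitor such as PR619, and their combinations — over a
short time course (10–180 min), and quantifies tens of thousands of
diGly sites (or, in tag-based pulldowns, thousands of substrate proteins)
by label-free intensity across 3–5 biological replicates per condition.

ubidyn implements the downstream statistics of such an experiment as a
reusable, tested pipeline: identification filtering, left-censored
imputation, moderated permutation-FDR testing of treatment-versus-control
contrasts, substrate dynamics classification, ubiquitin/Ubl chain-linkage
profiling, and positional motif analysis. A synthetic-data generator with
known ground truth replaces the raw instrument data, so every stage can be
verified quantitatively.

## The intensity model and its assumptions

All intensities are log2-transformed; zero or blank raw values are treated
as missing before transformation. The generator draws the log2 intensity of
entry $i$ in sample $j$ as

$$y_{ij} = \mu_i + \delta_{i,t(j)} + \varepsilon_{ij}, \qquad
  \varepsilon_{ij} \sim N(0, \sigma^2),$$

where $\mu_i$ is the entry's baseline, $\delta_{i,t}$ a planted
per-treatment log2 effect (zero for the control and for null entries), and
$\sigma$ the replicate noise. Defaults are $\mu = 25$ and $\sigma = 0.25$
log2 units — typical scales for label-free quantification — and a planted
effect of 2 log2 units (fourfold); all are parameters. Effects are applied
identically at every timepoint unless a per-timepoint profile is supplied,
which keeps ground-truth recovery unambiguous while still allowing
time-resolved profiles to be planted.

Missingness is modelled as left censoring (missing-not-at-random): a cell
with true intensity $I$ is dropped with probability
$\mathrm{logit}^{-1}((\ell - I)/s)$, by default located at
$\ell = \mu - 1.5$ with scale $s = 0.3$. Low-abundance measurements
therefore vanish preferentially, which is the standard assumption behind
down-shifted Gaussian imputation in this field. The generator does *not*
emulate peptide detectability, retention-time effects, batch structure,
ratio compression, or shared-peptide quantification ambiguity — passing
tests demonstrate correctness of the statistical machinery under the
declared model, not robustness to every artefact of real acquisitions.

## Identification filters

Three completeness conventions are implemented in
`filter_valid_values()`, matching the three acquisition designs:

* per-contrast complete-in-group ("DDA"): an entry enters a
  treatment-versus-control test when it is fully observed in all replicates
  of the treatment group or of the control group;
* complete in at least one group ("DIA", 5 replicates);
* at least $k$ observed values in some group ("His10" protein pulldowns,
  $k = 3$).

Decoy, contaminant and (for protein tables) only-identified-by-site entries
are removed by `filter_flags()` first. For Venn-style summaries of
treatment-exclusive identification (`venn_membership()`), "identified"
means observed in at least one replicate *before* imputation — imputed
values never create identifications.

## Imputation

`impute_left_censored()` replaces missing cells per sample column by draws
from $N(\hat\mu_j - d\,\hat\sigma_j,\ (w\,\hat\sigma_j)^2)$, where
$\hat\mu_j$ and $\hat\sigma_j$ are the column's observed moments. The
defaults $d = 1.8$ (downshift) and $w = 0.3$ (width) are the established
defaults of the desktop proteomics platforms this workflow mirrors; both
are exposed as `imputation_params()`. Imputation is per column because
censoring is an acquisition property of each run, not of each entry.
Imputation is applied after the valid-value filter of each analysis; the
run log records the order and the parameter values. Observed cells are
never altered, and a column with fewer than two observed values is an
error rather than a silent guess.

## The moderated permutation test

For a contrast of treatment ($n_A$ replicates) versus control ($n_B$), each
entry gets

$$t_{S_0} = \frac{\bar{x} - \bar{y}}{s + S_0},$$

with $s$ the classical pooled-variance two-sample standard error and $S_0$
a fudge constant (default 0.1) that de-emphasises entries whose tiny
variance would otherwise produce huge statistics at negligible
fold-changes. With $S_0 = 0$ the statistic is exactly Student's t, which is
asserted against `t.test()` in the test suite. Pooled variance is used
rather than Welch's, matching the "Student" label of the convention this
reproduces; the replicate design is balanced in practice.

The null distribution comes from permuting the group labels. All
$\binom{n_A + n_B}{n_A}$ relabelings are enumerated whenever that count is
at most 10,000 (always, for the 3v3 and 5v5 designs used here: 20 and 252);
otherwise 250 random relabelings are drawn under the configured seed and
the $(b+1)/(N+1)$ small-sample correction is applied. Per-entry p-values
count permuted statistics at least as extreme as the observed one, with a
$10^{-8}$ tie tolerance so that exact mirror-image ties (e.g. zero-variance
groups) are counted deterministically.

q-values follow the SAM convention: entries are ranked by decreasing
$|t_{S_0}|$ (signed statistic for right-sided tests; ties broken by entry
id so results are invariant to input row order), the estimated FDR at rank
$i$ is the mean number of pooled permuted statistics exceeding the rank-$i$
threshold per permutation divided by $i$, and q-values are the running
minimum from the bottom of the ranking, capped at 1. No $\pi_0$ estimate is
applied; with a large null fraction this makes the procedure mildly
conservative, which the all-null calibration test quantifies. The exact
q-value internals of the desktop platforms are not published, so numerical
agreement with them is not claimed — the procedure here is declared,
seeded, and oracle-tested instead.

The protein-level parental gate (`his10_substrate_gate()`) is a one-sided
(right) two-sample Student test at unadjusted $p < 0.05$: it asks only
whether a protein is detectably enriched in the tagged pulldown over the
untagged background before any treatment contrast is examined. The
"two-way right-sided" phrasing sometimes used for this gate is ambiguous;
it is implemented as the one-sided two-sample test, and the alpha is a
parameter.

## Dynamics classification and summaries

`classify_profile()` labels a substrate from its per-timepoint log2
fold-changes versus control: `Enriched` if any timepoint exceeds +1
(more than twofold), `Depleted` if any falls below −1, both labels when
both occur, `Unchanged` otherwise. The thresholds are strict inequalities
(a literal reading of "more than twofold") and configurable. Fold-changes
feeding the classification are the post-imputation mean differences from
the test results. Cross-treatment tables (`cross_tabulate()`) report, for
each group under treatment A, the percentage distribution of those
substrates' status under treatment B, with substrates absent from B counted
as `Not identified`; dual-labelled substrates count under `Enriched`, a
tie-break that matters only for the rare dual assignments.

## Chain-linkage topology

Mapping diGly peptides onto the bundled mature Ub/Ubl sequences
(`map_modified_peptide()`) is exact substring search — search engines
report peptides verbatim from the database, so approximate matching would
only create false localisations. A peptide matching several homologs (the
C-terminal halves of mature SUMO2 and SUMO3 are identical) yields one
record with a joint accession set and the offset position pair
(e.g. SUMO2/SUMO3-K44/45); only matches of the *same* peptide are merged,
never matches of distinct peptides. The bundled references are the mature,
conjugatable forms truncated at the C-terminal diGly — Ub (76 aa), NEDD8
(1–76), SUMO1 (1–97), SUMO2 (1–93), SUMO3 (1–92) — because diGly chemistry
acts on the processed proteins; the one-residue N-terminal offset between
mature SUMO2 and SUMO3 is what produces the familiar K20/21, K32/33,
K44/45 paired numbering. Users supplying their own FASTA should check that
their sequences are mature forms, or the lysine numbering will shift.

`ubl_homology()` compares two sequences position-wise when they are of
equal length and globally aligns them first otherwise (match +1, mismatch
0, gap −1). Identity is the fraction of identical alignment positions.
For similarity, no single convention exists; the package declares one:
a position is similar when its residue pair has a non-negative score in
the substitution matrix, with BLOSUM80 as the default matrix. BLOSUM80 is
the appropriate "hard" matrix for closely related sequences (mature Ub and
NEDD8 are ~58% identical), and under this convention their similarity is
80% — the figure conventionally quoted for this pair. Both the matrix and
the strictness are parameters, and the pairing is symmetric by
construction.

## Motif profiles

Sequence context is the 31-mer window (±15 residues) around the modified
lysine, padded with `_` at protein termini; padding is excluded from
frequency denominators and the centre must be a lysine.
`frequency_fold_change()` compares two profiles as
$\log_2\!\big((f_{fg} + c_{fg}) / (f_{ctrl} + c_{ctrl})\big)$ with a
per-profile pseudocount $c = 1/(n_{\text{windows}} + 20)$, so identical
profiles give an exactly zero matrix and absent residues stay finite with
a magnitude bounded by the pseudocount. The background set
(`select_control_sites()`) contains sites observed in every control
replicate and significant in no treatment. The treatment-exclusive
selection (`select_top_exclusive()`) ranks sites by fold-change in one
treatment and keeps those below 1 log2 unit (less than twofold) in the
other, truncated to the top 100 by default; the "less than onefold"
phrasing of this rule is interpreted in log2 units, consistent with every
other fold-change in the workflow — the raw-scale reading would be a
different (and degenerate) filter. Windows are counted once per distinct
site; no multiplicity weighting is applied.

## Numerical and design choices

* **Determinism.** Every stochastic step (simulation, imputation, sampled
  permutations, k-means) takes an explicit seed; `run_pipeline()` writes a
  manifest of MD5 content hashes, and two runs with the same configuration
  produce identical manifests.
* **Ties.** Ranked statistics break ties by entry id; permuted-statistic
  comparisons use a $10^{-8}$ tolerance.
* **Degenerate inputs.** Zero-variance groups are handled by the $S_0$
  denominator; empty profiles, empty FASTA records, constant vectors in
  correlations, and columns with fewer than two observed values are
  errors with informative messages rather than NaNs.
* **Clustering.** The heatmap ordering reproduces the k-means-then-
  hierarchical convention (default k = 300, 1000 iterations; Euclidean
  distance, average linkage on the centroids), which scales to tens of
  thousands of rows; with k equal to the row count it degenerates to plain
  hierarchical clustering, which the tests assert.
* **PCA** is mean-centred and unscaled, on the samples of the complete
  (post-imputation) matrix.

## Problem sizes used in the tests

The simulation-based checks run at 2,000 entries with 5 versus 5
replicates for calibration and power (exact enumeration of all 252
relabelings), 10,000 imputed cells for the imputation moments, and the
full 39-lysine Ub/Ubl complement for linkage recovery. These sizes give
Monte-Carlo standard errors comfortably below the asserted tolerances
(e.g. $3\sigma/\sqrt{n}$ bounds are used explicitly) while keeping the
whole suite fast.

## Known limitations

* The permutation-FDR internals of the desktop platforms this mirrors are
  undocumented; q-values here are SAM-style as specified above and may
  differ numerically from theirs on the same data.
* No localisation-probability cutoff is applied to site tables; users of
  search-engine output with localisation scores should pre-filter.
* Imputation can inflate apparent enrichment of sites identified
  exclusively in one treatment (a known property of left-censored
  imputation); the Venn summaries therefore use pre-imputation
  identification only.
* Surface-accessibility prediction and network/enrichment analyses are out
  of scope; the package produces the site selections and randomised
  peptide controls that feed such external tools.
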