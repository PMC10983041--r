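---
title: "Gene-centric integration of SV breakpoints with tumor expression and survival"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-centric integration of SV breakpoints with tumor expression and survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(svimpact)
```

## The problem and the approach

Structural variants (SVs) — deletions, duplications, inversions and
translocations described by a pair of breakpoints — can alter the expression
of nearby genes through gene disruption, dosage change, or cis-regulatory
rewiring. `svimpact` implements a *gene-centric* integration of SV
breakpoints with tumor expression and patient survival: instead of testing
each variant (the eQTL view), it asks, for every gene and a small set of
genomic region windows anchored on that gene, whether samples carrying *any*
breakpoint in the window express the gene differently, and whether that
breakpoint pattern carries survival information. Gene-centric testing
aggregates distinct variants hitting the same region, keeps the multiple-
testing burden at the number of genes, and finds associations that cut
across tissues of origin.

The pipeline has five stages, each a module of exported functions:

1. **Call-set harmonization** (`merge_callsets`): germline calls from two
   callers are pairwise joined per patient, requiring both breakpoints to
   agree within 200 bp (inclusive slop). Matching is one-to-one, greedy by
   ascending total breakpoint distance, and the coordinates of the first
   call set are kept. One-to-one matching was chosen because many-to-many
   joins would double-emit calls and inflate downstream recurrence counts.
2. **SV landscape** (`summarize_svs`, `compute_recurrence`,
   `cytoband_enrichment`, `copy_category_crosstab`): class mix, median
   intrachromosomal size, cross-patient breakpoint recurrence at 10 bp slop,
   per-patient cytoband density, and the copy-number footprint of
   gene-spanning duplications/deletions.
3. **Breakpoint matrices** (`build_breakpoint_matrix`,
   `build_weighted_matrix`): gene x sample matrices per window.
4. **Association** (`run_associations`): per-gene linear models of log2
   expression on the breakpoint pattern under three covariate models, with
   Benjamini-Hochberg FDR inside each window's tested gene set.
5. **Mechanism and survival** (`classify_enhancer_duplication`,
   `sv_class_direction_enrichment`, `cross_essentiality`,
   `cox_breakpoint_scan`, `derive_signature`, `tscore`,
   `signature_survival`).

All intervals are 0-based half-open; breakpoints are single base offsets;
slop comparisons are inclusive. Converters handle 1-based input tables.

## Windows and the breakpoint matrix

Six windows are supported: `gene_body` (`[start, end)`), `up_100kb` /
`down_100kb` / `up_2kb` (strand-aware flanks; *upstream* means 5' of the
gene on its own strand), `utr3` (the annotated 3' UTR; genes without one are
skipped for this window), and `flank_1mb_weighted`. Unweighted entries are
1 iff any breakpoint of any SV of the sample falls in the window — both
breakpoints of an SV count independently, translocation mates on their own
chromosomes, and SV class plays no role. Flank windows exclude the gene body
so that the same geometry is never coded twice; a breakpoint inside the gene
contributes to `gene_body`/`utr3` only.

The weighted 1 Mb window follows the "relative distance" idea: nearer
breakpoints should weigh more. For each (gene, sample) the entry is
`1 - d/extent` where `d` is the distance from the gene start
(transcription start site, strand-aware) to the sample's nearest breakpoint
on that chromosome, zero beyond the extent. The linear form is a deliberate,
transparent stand-in — the upstream literature specifies only the monotone
intent, not a functional form — and the weight function is isolated in
`build_weighted_matrix` so it can be swapped.

## The association model

For gene *g* with breakpoint vector *b* (0/1 or weights) over samples, the
model is

```
log2(expr + 1) ~ b [+ tissue + copy_number + ploidy + purity]
```

fit by ordinary least squares; the reported p is the two-sided t test of the
coefficient of *b*. Three covariate models are exposed (`none`, `tissue`,
`full`) because the tissue term matters qualitatively: recurrent germline
SVs can be enriched in particular tissues, and tissue also drives baseline
expression, so the uncorrected model mistakes tissue structure for SV
effects. With `model = "none"` and binary *b* the p value is exactly the
pooled-variance two-sample t test — a closed-form identity the test suite
asserts to 1e-10.

Choices worth knowing:

* The log transform is fixed at `log2(x + 1)`; the pseudocount keeps zeros
  finite and the base matches effect sizes expressed in fold changes.
* Tissue enters as treatment contrasts against the most frequent tissue;
  the breakpoint coefficient's p is invariant to the reference choice.
  Single-tissue cohorts drop the term with a warning.
* Copy number enters as raw copies with ploidy as a separate covariate
  (rather than a ploidy-ratio), matching the covariate list as usually
  stated.
* Genes with fewer than `min_carriers = 3` carriers in a window are
  excluded *before* FDR estimation; BH is applied within each
  (window, model) tested set, never pooled across windows.
* Rank-deficient designs and constant expression yield records flagged
  untestable (`p = NA`, excluded from BH) rather than errors.

## Mechanism layers

**Enhancer duplication.** An SV counts as a flanking enhancer duplication
for a gene iff all five conditions hold: it is a duplication; both
breakpoints lie in the 100 kb flank; neither breakpoint is inside the gene;
the SV does not span the gene; and the SV interval contains at least one
whole enhancer (partial overlap is available behind a flag, off by default —
"spanning" an enhancer is read as containment). Enrichment of this class
among significantly up-regulated genes is a Pearson chi-squared test
(no continuity correction) over (gene, SV) pairs in the window.

**Copy categories.** Gene-spanning DUP/DEL events are cross-tabulated
against ploidy-corrected copy number, `copies * 2 / ploidy`, binned at the
conventional cutoffs: amplification (> 5), copy gain ([3, 5]), copy loss
([0, 1]), neutral in between; boundaries are exact and tested.

**Cytobands.** The per-patient test is a 1-df chi-squared of the patient's
in-band vs out-of-band breakpoint counts against the expectation
proportional to the band's share of genome length. A per-band test (rather
than one genome-wide goodness-of-fit per patient) is required so the cohort
summary can count, per band, the patients in which it is enriched.

## Survival and the signed signature

Breakpoint patterns are carried into Cox proportional-hazards models
stratified by cancer type (separate baseline hazard per stratum, Breslow
ties — the ubiquitous default, stated so oracle comparisons match). Because
absence of a germline variant should not shorten survival, gene selection
demands a *positive* association: one-sided `p = p_two/2` if the
coefficient is positive, else `1 - p_two/2`.

A gene enters the signed signature iff, for at least one window, its
breakpoint pattern is positively associated with worse survival (one-sided
p < 0.05) *and*, for at least one window, associated with altered
expression (two-sided p < 0.05). The gene's sign is the direction of its
most significant expression association (ties broken by larger effect).
The windows scanned are gene body, both 100 kb flanks, and the weighted
1 Mb flank.

A sample's signature score is the pooled-variance two-sample t statistic
comparing its values over the signature's +1 genes versus its -1 genes,
computed on per-gene cohort-mean-centered log2 expression
(`center_log_expression`) — the "differential profile". The t form makes
the score invariant to profile shifts and positive rescaling, and
antisymmetric under direction reversal. Score-outcome separation is tested
two ways: a stratified log-rank test across score tertiles (empirical 1/3
and 2/3 quantiles; heavily tied scores are an error, not a silent
collapse) and a stratified Cox model on the continuous score.
Expression-survival models use unstandardized log2 expression.

## What the synthetic cohort emulates

Every stage is validated against `simulate_study_cohort()`, whose defaults
are the package's study conditions:

* **Genome**: 4 chromosomes x 50 Mb, 1,000 non-overlapping genes (5-100 kb,
  random strand, half with a 3' UTR at the strand-appropriate end), 300
  enhancers, 10 cytobands per chromosome tiling it exactly.
* **Germline SVs**: a population panel of 1,000 SVs with per-SV carrier
  frequency uniform on [0.05, 0.5]; Bernoulli carrier draws per patient make
  calls highly recurrent across patients, emulating common inherited
  variation. Class mix 78% DEL / 12.5% INV / 9.3% DUP; sizes log-normal with
  2.1 kb median (the log-normal is a modeling choice — only the median is
  constrained by observation). The panel size trades realism (hundreds of
  SVs per patient; real germline call sets run into the thousands) against
  desk-scale runtime, and keeps panel-level sampling noise in the class mix
  well inside the tolerances the tests assert. Eight percent of the panel
  concentrates in one cytoband, emulating SV hotspots.
* **Two callers**: caller B equals caller A with per-breakpoint uniform
  jitter on [-50, +50] bp (well inside the 200 bp merge slop) and 5%
  per-call dropout.
* **Somatic SVs**: Poisson(20) private events per patient, 24%
  translocations, 175 kb median size — rare, large, non-recurrent, the
  opposite regime from germline.
* **Planted truth**: 30 gene-body cis-effects of +1 log2 at panel-SV
  carriers; 8 upstream enhancer-spanning duplication effects; 5 genes with
  both germline and somatic events (for the overlap stage); survival
  hazards of log HR 0.5 per carrier on the first 10 effect genes (enough
  genes that the derived signature, not a single marker, carries the
  survival signal).
* **Expression**: `log2 expr = baseline(gene) + tissue offset (SD 1) +
  effect x carrier + N(0, 0.5)`, emitted on the linear scale as `2^y - 1`
  so the pipeline's `log2(x+1)` recovers y exactly; baselines on [4, 8]
  keep the linear values effectively never truncated at zero. Copy number
  fluctuates around ploidy (uniform [1.5, 4.5]; purity uniform [0.3, 1])
  and is dented by gene-spanning somatic DUP/DEL events, so the somatic —
  but not germline — copy crosstab shows the expected gain/loss pattern.
* **Survival**: exponential event times with hazard
  `0.02 x exp(sum log HR x feature)` per month, independent exponential
  censoring calibrated to ~30% at baseline, follow-up capped at 120 months
  (event cleared at the cap).

What it does **not** emulate: read-level data or SV calling artifacts
beyond jitter/dropout, mobile-element insertions, linkage between SVs,
copy-number-driven germline expression effects, non-exponential hazards,
tissue-specific effect sizes, and correlated gene-gene expression
structure. Passing tests therefore demonstrate that the statistical
machinery recovers known truth under its own model assumptions — they do
not certify performance on real cohorts, where effect sizes are smaller
and confounding richer.

## Numerical and degenerate-input policy

* Determinism: every simulator takes a seed and is bytewise reproducible.
* Untestable fits (constant feature, < 2 events, rank deficiency) are
  flagged, never silently dropped or crashed.
* Chi-squared results carry `degenerate` (zero margin: p absent) and
  `low_expected` (expected cell < 5) flags.
* The t-score requires >= 2 genes per side; zero-variance profiles return 0
  (equal means) or signed infinity, flagged.
* Merge ties (equal total distance) are broken by input order, making the
  greedy match deterministic.

## Problem sizes

The validation suite runs the full default cohort (400 patients, 1,000
genes, ~110,000 merged germline calls) end to end twice for the determinism
check, recovery simulations at 10-20 seeds each, and brute-force oracle
comparisons up to 100 genes x 100 samples x 1,000 SVs. These sizes were
chosen so the entire suite completes in a few minutes on one core while
leaving the statistical assertions (sensitivity >= 0.9, FDP <= 0.15, null
uniformity, 80-90% per-seed power) well-powered.

## Known limitations

* The weighted-window form is linear by construction, not estimated.
* The per-patient cytoband test assumes breakpoints are exchangeable across
  the genome under the null; clustered SV classes violate this mildly.
* `overlap_germline_somatic` intersects fixed thresholds (p < 0.01); no
  joint model of the two origins is fit.
* Cox models here are single-feature (plus strata); no multivariable
  clinical adjustment is attempted.
* The catalog-overlap matcher supports breakpoint slop only; reciprocal-
  overlap matching is not implemented.
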