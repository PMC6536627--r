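---
title: "Methods: template-pattern analysis of stress-responsive transcripts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: template-pattern analysis of stress-responsive transcripts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stresspatterns)
```

## The scientific setting

Chronic stress changes how the hypothalamic-pituitary-adrenal (HPA) axis
and the hippocampal transcriptome respond to a *new* stressor, and the
change depends on genotype. The design this package analyzes crosses
three inbred mouse strains (B = C57BL/6J, N = C57BL/6NJ, D = DBA/2J)
with four treatment histories: normal housing (NH), chronic mild stress
(CMS), and each of those followed by a novel 15-minute acute restraint
(NH-R, CMS-R). Strains B and N are near-identical substrains while B and
D are highly divergent, so agreement between B and N and divergence of D
is the expected genetic signature.

## The template model

For each transcript within each strain, expression across the ordered
stress-exposed groups (CMS, CMS-R, NH-R) is compared to two predicted
response shapes:

- **transient**, `0:1:0` — elevated only when the acute stressor follows
  chronic stress (the cross-sensitization pattern);
- **sustained**, `1:1:0` — elevated in every chronic-stress history.

Down-regulation is the *inverse* of each shape (`1:0:1` and `0:0:1`).
The fit regresses log2 expression on the single binary template
indicator:

$$ y_{ij} = \beta_0 + \beta \, x_j + \varepsilon_{ij}, \qquad
   \varepsilon_{ij} \sim N(0, \sigma^2), $$

with a two-sided t-test on the slope at df = n − 2. Two consequences
drive the implementation:

1. with a binary regressor the slope test is *algebraically identical*
   to the pooled-variance two-sample t-test grouping samples by the
   indicator — this equivalence is the oracle the test suite checks to
   1e-10;
2. an inverse pattern is exactly a sign flip of the slope, so one fit
   per shape covers both orientations, and direction is simply
   `sign(beta)`.

The NH group is excluded from template fitting: the templates are
defined only over the three stress-exposed histories, and NH serves the
phenotype analyses. This was a genuinely open choice (one could include
NH as a second reference level); the exclusion keeps the model identical
to the quoted pattern encoding and makes the two orientations exact
mirror images.

A transcript is **called** stress-responsive in a strain when

- its better template fit has nominal p ≤ 0.05 (`alpha`),
- the Welch unequal-variance NH-R vs CMS-R contrast has p < 0.05, and
- the linear-scale relative change
  $2^{\overline{\log_2 \text{CMS-R}} - \overline{\log_2 \text{NH-R}}} - 1$
  strictly exceeds 10% (`fc_threshold`) in the called direction.

BH q-values over the best-template p-values are computed per strain and
reported, but do not gate the calls: at 4–5 replicates per cell few
transcripts survive an FDR threshold, so the nominal threshold plus the
effect-size filter is the descriptive criterion, with q available to the
reader. The 10% change is evaluated on the linear (unlogged) scale with
a strict inequality; whether the original filter used log2 or linear
units was unstated, and linear is the reading consistent with "fold
change". Ties between shapes (equal p) go to the larger |t|, then to
TRANSIENT — deterministic and documented. Zero-variance transcripts
return β = 0, p = 1 rather than erroring, so all-flat fixtures flow
through the pipeline.

Direction bias per strain is tested with a 1-df goodness-of-fit
chi-square against a 50:50 split, $(n_{up}-n_{down})^2/(n_{up}+n_{down})$.
With a single classification variable a goodness-of-fit test is the
defensible reading even where an "independence" test is colloquially
named.

## Overlap, concordance, clustering

Calls are partitioned into the seven *exclusive* Venn regions of the
three strains; pairwise regions exclude the triple region, the
convention under which the motivating study's printed counts
(430 + 258 + 1363 + 9 + 31 + 130 + 6) sum to its printed union of 2,227.
Concordance for a pair or triple counts transcripts called in the same
direction in all requested strains. Shared (multi-strain) transcripts
are clustered on a 3-vector of per-strain contrasts (mean CMS-R − mean
NH-R), not the full sample matrix: the strain-level contrast is the
displayed quantity of interest and the reduced feature stays defined
under unequal replicate counts. Clustering is agglomerative with average
linkage on Euclidean distances; rows are pre-sorted by transcript id so
leaf order is deterministic, and the tree is exported as Newick.

## Phenotype statistics

Restraint does not affect biometrics, so treatments are pooled into
CMSgroup (CMS, CMS-R) vs NHgroup (NH, NH-R) for body/organ-weight
analyses; raw (uncorrected) tissue weights are analyzed by explicit
choice of the motivating design. The two-way ANOVA uses Type III
(partial) sums of squares under sum-to-zero contrasts — Type III is
coding-dependent and sum-to-zero is the convention that makes it
meaningful — computed via `car::Anova(type = 3)`, with
η² = SS(term)/SS(total, corrected) as effect size. When a model fits
exactly (zero residual SS, as in constructed fixtures) the partial SS
are computed directly by dropping each term's columns from the
sum-to-zero design, since the standard F machinery is undefined there.
Post-hoc contrasts use Welch's unequal-variance t-test with
Welch–Satterthwaite df; if both groups are constant the test degenerates
to t = 0, p = 1 (equal means) or p = 0 with a warning (unequal means).

Plasma CORT is screened by a *single-pass* 2-SD rule within strain ×
treatment groups (mean and SD computed on the full group, groups of
n < 3 untouched); a single pass, not iterated, matches a one-shot
technical-artifact screen. Weekly fecal CORT is natural-log transformed
(the base affects neither F nor p; natural log fixes the transformed
values for reproducibility) and analyzed as strain × week with week
categorical. Repeated measurements within animal are not modeled — the
analysis is replicated as designed, and that limitation is inherited
knowingly.

## Enrichment

Over-representation is an upper-tail hypergeometric test per category,
restricted to the background universe, with categories below 5
in-background members excluded *before* testing and BH adjustment run
over the tested categories only (excluding small sets changes the
correction family — intentional and documented). The ≥ 5 criterion is
interpreted as in-background category size, the convention of the web
tools this replaces, not overlap size. Only the one-sided
over-representation direction is tested.

## What the generators emulate — and what they do not

`simulate_expression` draws per-transcript baselines uniformly over
4–12 log2 units and adds Gaussian residuals (SD 0.25 log2 units, the
conventional microarray noise model on the log scale). Planted
transcripts shift their strain's template groups by ±1.0 log2 units.
Membership is assigned by explicit index blocks — multi-strain overlap
blocks (defaults 9, 31, 130, 6) first, then strain-exclusive blocks
(fractions 0.017, 0.010, 0.053 of the universe, echoing unique counts of
~430/258/1363 at 25,858 transcripts) — so exact region counts are
achievable for fixtures. Direction follows per-strain up-biases (B 0.5,
N 0.7, D 0.3) and shared transcripts agree across a strain pair with the
configured concordance probability (B:N 1.0, B:D 3/31, N:D 15/130).
Replicates per cell default to 5, within the study's stated four-to-five
per group; the exact per-strain counts were not printed, so the value is
a config knob rather than a constant.

`simulate_phenotypes` and `simulate_fcort_timecourse` reproduce the
printed quantitative anchors — heart-weight CMS deficit 10.4 mg,
baseline fCORT means/SDs (B 1.77 ± 0.20, N 1.73 ± 0.27, D 1.93 ± 0.22),
habituation back to baseline by week 4 — and the printed *orderings*
(heart D > N > B; thymus and adrenal N > B > D; brain B ≈ N > D;
CMS-attenuated weight gain in B and N only; restraint CORT larger in N
and D; an N-only CMS-R sensitization increment). Where a mean or SD was
not printed (organ-weight means, plasma-CORT levels, the week-1 fCORT
elevation of 1.6×), values were fixed once at magnitudes typical for
adult female mice of these strains and are exposed in `pheno_config()`.
The fCORT trajectory is simulated on the natural scale with a linear
decline from the week-1 peak to baseline at the return week; the log
transform belongs to the analysis, mirroring the real order of
operations.

The generators deliberately do **not** model probe-level effects, RMA
normalization, array outlier removal, batch or sacrifice-day covariates,
estrus cycle, heavy-tailed noise, or within-animal correlation of weekly
fCORT. Passing recovery tests therefore demonstrate that the pipeline's
inference machinery is correct and calibrated under its own assumptions,
not that those assumptions hold for any particular real dataset.

## Numerical and testing choices

- Template-fit p-values are validated against an independent textbook
  pooled-t implementation at 1e-10 over 1,000 random designs; BH against
  a brute-force step-up; Welch and balanced Type III ANOVA against hand
  formulas; the hypergeometric tail against exhaustive enumeration of
  all C(20,5) draws; average linkage against hand-computed merge
  heights (the 0/1/10 profile example with heights 1 and 9.5).
- Null calibration uses 10,000 unplanted transcripts: each shape's
  p ≤ 0.05 rate must sit within 3 binomial SEs of 0.05, and the min-p
  candidate rate over both (correlated) shapes is checked against an
  independent Monte Carlo estimate.
- Recovery uses 8,000 transcripts at the default effect (1.0 log2), SD
  (0.25) and 5 replicates — a standardized difference large enough that
  a two-sample t power calculation predicts essentially full power, so
  the suite requires sensitivity ≥ 0.90 and direction accuracy ≥ 0.99
  among recovered calls. These problem sizes keep the whole suite fast
  while leaving the binomial error bars far smaller than the margins
  being asserted.
- All generators consume a single integer seed; identical seed and
  config produce bit-identical outputs, and the pipeline manifest
  records the seed and thresholds of each run.

## Known limitations

- The linear model carries no covariates; if real data have batch
  structure, it must be removed upstream.
- The fCORT ANOVA treats weekly measures as independent; a
  repeated-measures or mixed model would be more efficient and is out of
  scope by design.
- η² values are reported per term against the corrected total SS; in
  unbalanced designs Type III SS do not sum to the total, so η² values
  need not sum to 1.
- The enrichment module ships no curated annotation databases; results
  depend entirely on the supplied GMT collections.
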