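---
title: "Plasma DNA copy-number screening: models, calibration and design choices"
author: "cfScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plasma DNA copy-number screening: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfScreen)
```

## The screening problem

High-grade serous ovarian carcinoma (HGSOC) is defined by chromosomal
instability: most tumors carry multiple arm-level gains (3q, 8q, 20q, ...)
and losses (5q, 8p, 13q, ...). A fraction of a patient's plasma cell-free
DNA (cfDNA) is tumor-derived, so those dosage imbalances leave a faint,
genome-wide imprint on shallow whole-genome sequencing of plasma — the same
data type clinical NIPT platforms produce at 0.2–0.3x coverage (18–28 M
36 bp reads). `cfScreen` implements the analysis layer of such a screen:

1. a **within-sample-reference CNV caller** that scores each genomic bin
   against bins chosen to behave like it in unaffected samples;
2. the **prespecified screen rule**: any called segment ≥ 15 Mb makes the
   subject screen positive;
3. **catalog annotation** of calls against recurrent HGSOC arm events;
4. a simplified **NIPT-style whole-chromosome screen** with no-call logic;
5. **evaluation** with exact (Clopper–Pearson) binomial intervals;
6. a seeded **synthetic-cohort generator** used for all calibration and
   power checks.

## The count model the generator emulates

Counts are simulated per usable bin $i$ of a fixed grid (1 Mb bins on an
hg19-like 22+X genome by default; trailing partial bins under half a bin
are kept but flagged unusable and excluded from every statistic):

$$w_i = m_i \cdot \max\{1 + s\,(g_i - 0.41),\ 0.1\} \cdot
        \left(1 + \mathrm{tf}\,\frac{c_i - 2}{2}\right), \qquad
  \mathrm{count}_i \sim \mathrm{NB}\!\left(\mu = N \frac{w_i}{\sum w},\ r\right)$$

* $m_i = e^{\eta_i}$, $\eta_i \sim N(0, 0.1^2)$ — bin baseline weights,
  fixed per grid (mappability-like structure);
* $s \sim N(0, 0.5^2)$ — a per-sample linear GC bias slope around the
  genomic mean GC of 0.41, floored at 0.1;
* $N \sim U(18\cdot10^6, 28\cdot10^6)$ — total reads, the platform's range;
* $r = 1000$ — negative-binomial dispersion; at typical bin means
  (~7,000 reads) this gives variance about 8x Poisson, a shallow-WGS-like
  overdispersion;
* $c_i$ — the truth copy number covering the bin (2 outside events; a
  boundary bin takes the copy number covering the majority of the bin),
  diluted by the tumor fraction tf through the standard linear plasma
  mixture $1 + \mathrm{tf}(c-2)/2$.

Counts are drawn as `qnbinom(u, ...)` from one seeded uniform stream, so a
fixed seed yields byte-identical cohorts, a tf = 0 case is *identical* to
the copy-neutral sample with the same seed, and changing only the read
depth preserves the randomness stream (this is what makes the NCV
depth-invariance check meaningful).

Tumor truth profiles draw each catalog arm independently with probability
equal to its tumor frequency (gain → copy 3, loss → copy 1), plus
Poisson-many focal events of 1–10 Mb; overlaps keep the earlier-drawn
event. Case tumor fractions default to $U(0.02, 0.15)$ for early-stage and
$U(0.05, 0.30)$ for advanced-stage cases — the study's real tumor
fractions are unknown, so these are exercise parameters chosen to span
barely-detectable through comfortable signal, not estimates.

**What the generator does not emulate:** fragment-length (size-selection)
signal, mappability/sequencing-error structure, subclonal mixtures,
germline CNVs, and waviness beyond a linear GC response. Passing
calibration tests on these simulations therefore demonstrates internal
consistency of the method, not clinical performance on real plasma.

## The caller

**Normalization.** Usable-bin counts are divided by the usable *autosomal*
total; X bins are scored on the same scale but never contribute to the
denominator (an all-female screening population has variable X dosage that
must not perturb autosomal values, yet monosomy X must stay scorable).

**GC correction.** A loess fit (span 0.3, degree 2) of value against bin
GC over usable autosomal bins; every usable bin is divided by the fit at
its GC (clamped to the fitted range) and values are renormalized. The
correction is applied at most once — re-running `gcCorrect()` is a no-op,
because a second statistical pass would only re-fit ~0.1%-level noise
wiggle. Fewer than 50 usable bins skips correction with a warning.

**Reference index.** For bins $i, j$ the panel distance is
$d(i,j) = \sum_s (v_{si} - v_{sj})^2$ over normalized, corrected panel
samples. Each usable bin's reference set is the $k = 100$ nearest eligible
bins (ties broken by grid order). Eligibility excludes the bin itself,
every bin on the same chromosome (so whole-chromosome events are not
self-normalized away), and chromosome X. The scored statistic is the
reference ratio $r_i = v_i / \operatorname{mean}(v_{\mathrm{ref}(i)})$,
standardized by panel moments $\mu_i, \sigma_i$ (with
$\sigma_i \ge 10^{-4}\mu_i$ as a numerical floor).

**Leave-one-out calibration.** $\mu_i$ and $\sigma_i$ are estimated with
the held-out sample's references re-selected on the remaining panel
(implemented in C++; the scoring references always come from the full
panel). This matters: selecting references and measuring their spread on
the same samples lets the selection fit panel noise, understating
$\sigma_i$ by ~17% and inflating every fresh-sample z-score to sd ≈ 1.18.
With leave-one-out calibration, null per-bin z-scores have sd ≈ 1.01 on a
50-sample panel.

**Windows and segments.** Individual z-scores are combined by Stouffer's
method over a centered $w = 7$ bin window, truncated at chromosome ends
(windows never span chromosomes): $Z_i = \sum_{\mathrm{win}} z / \sqrt{|\mathrm{win}|}$.
Bins with $|Z| \ge 3.5$ are marked; same-sign runs bridging at most 2
unmarked bins become segments spanning first to last marked bin. No
sub-bin boundary refinement is attempted — at a 15 Mb decision threshold,
±1 Mb boundaries are immaterial and the size rule stays exactly testable.

**Panel size.** The default reference panel is 50 unaffected samples. The
platform multiplexes each run with ~14 clinical samples, but that is a
flow-cell layout, not a reference set; within-sample-reference callers and
NIPT baselines are typically built from several dozen to hundreds of
normals. Below ~20 samples the leave-one-out moments get noticeably noisy
(a warning fires below 10).

## The screen and annotation layer

A subject is screen positive iff any called segment has
$(\mathrm{end}-\mathrm{start})/10^6 \ge 15$ — inclusive, because the
screen's headline phrasing is "≥ 15 Mb" (its methods text says "> 15 Mb";
with 1 Mb bins and marked-bin-span boundaries the distinction only affects
exactly-15 Mb segments, and the threshold is a parameter).

Segments are assigned every chromosome arm covering at least 25% of the
segment's length (a whole-chromosome segment maps to both arms), and each
(arm, direction) is classified against the catalog:
*q < 0.25 and frequency > 0.5* → highly specific; *q < 0.25, frequency
≤ 0.5* → moderately specific; otherwise non-specific. A segment's class is
the most specific among its arms; classification is a pure function of
(arm, direction, catalog), so catalog row order is irrelevant. The shipped
catalog reproduces the published summary *counts* (8 significant gained
arms, 5 of them at > 50% frequency; 22 lost, 18 at > 50%) with synthetic
q-values and frequencies covering the arms seen in the worked example —
the source atlas's exact per-arm numbers are not redistributed, and the
TSV is user-editable.

Focal aberrations are called segments under 15 Mb. At the default 3.5
threshold over ~3,000 windowed scores, a perfectly calibrated copy-neutral
sample still yields on the order of one spurious 1–2-bin call, so focal
counts separate cases (many true focal events) from controls on average
rather than absolutely; the ≥ 15 Mb screen layer showed zero false
positives across all null calibration runs.

## The aneuploidy arm

The routine prenatal pipeline is approximated by the normalized chromosome
value: $z_c = (f_c/s - \bar f_c)/\mathrm{sd}(f_c)$ against the panel, for
targets 13, 18, 21, X (Y is out of scope for an all-female cohort).
Thresholds: $|z| \ge 4$ calls high risk; any non-target autosome with
$|z| > 3$ triggers a no-call ("unexpected profile on normalizing
chromosomes"). Both are config defaults; reports flag the QC rule as an
approximation of proprietary pipeline logic.

The scale factor $s$ — the median over autosomes of the sample's
fraction/panel-mean ratios, applied symmetrically when building panel
statistics — deserves explanation. Chromosome fractions are compositional:
a tf = 0.3 monosomy 18 removes ~0.4% of the autosomal total, which
*inflates* every other chromosome's fraction by 2–4 panel sd under this
count model. Without the median-of-ratios rescaling, nearly every clean
monosomy-18 case would no-call on its "normalizing" chromosomes; with it,
the aberrant chromosome carries its own deficit ($z_{18} \approx -40$ at
tf 0.3) and euploid chromosomes stay near zero. The median tolerates
several genuinely aberrant chromosomes, which is why heavily rearranged
cancer-like profiles still flood QC and no-call — the behavior this screen
arm exists to demonstrate.

One structural consequence of the QC rule is worth stating plainly: with
19 non-target autosomes and threshold 3, a *perfectly* calibrated euploid
sample passes QC with probability $0.9973^{19} \approx 94.9\%$; finite
panels (t-tails) push the observed control low-risk rate to ~87–94%. A
stricter-than-5% false-no-call expectation is not achievable with this
rule at these thresholds; the package reports the measured rate honestly.

## Evaluation

Sensitivity and specificity are exact binomial point estimates with
two-sided Clopper–Pearson 95% intervals from beta quantiles (the method
reproduces the published intervals bit-for-bit on the worked example
counts 13/32 and 30/32; a tail-probability bisection oracle cross-checks
the bounds in the tests). Percentages are displayed half-up to one decimal
(93.75 → 93.8), full precision kept internally. Arm tallies count each
subject at most once per (arm, direction); whole-chromosome calls expand
to both arms for metacentric chromosomes and to the q arm only for the
acrocentrics (13, 14, 15, 21, 22).

## Problem sizes used in the checks

The bundled tests and the acceptance script run on the full default grid
(~3,050 bins) with a 50-sample panel: 20 null samples for calibration, 50
seeded replicates per spike-recovery and aneuploidy property, 100
replicates for the control low-risk rate, and a complete 64-subject
simulated cohort pushed end-to-end through files, caller, screen rule and
evaluation. Hand-checkable algebraic examples use 10–45-bin toy grids
where every quantity is verified against brute-force reimplementations.

## Known limitations

* Segment boundaries are bin-resolution; no sub-bin breakpoints, no CBS.
* Copy number is reported as direction only; no absolute quantification
  or tumor-fraction estimation.
* The catalog's q-values/frequencies are synthetic placeholders shaped to
  the published summary counts; users with access to the atlas's arm
  tables should substitute their own TSV.
* The simulation omits fragmentomics, mappability and germline CNVs; all
  statistical guarantees are with respect to the stated count model.
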