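# cfScreen

Screening plasma cell-free DNA (cfDNA) for the segmental copy-number
aberrations characteristic of high-grade serous ovarian carcinoma (HGSOC),
from the shallow whole-genome sequencing bin counts that clinical NIPT
platforms produce (0.2–0.3x coverage, 18–28 M single-end reads).

HGSOC tumors are chromosomally unstable — recurrent arm-level gains (3q,
8q, 20q, 12p, ...) and losses (5q, 8p, 13q, ...) — and a fraction of a
patient's plasma DNA is tumor-derived, so those imbalances surface as
small coherent shifts in binned read counts. `cfScreen` implements the
whole analysis layer of such a screen, for bioinformaticians evaluating
low-coverage plasma sequencing as a cancer screening modality:

* **CNV caller** — within-sample-reference z-scores: each usable 1 Mb bin
  is scored as the ratio of its normalized, GC-corrected value to the mean
  over its *k* = 100 reference bins (the other-chromosome bins that behave
  most like it across a copy-neutral panel), standardized by leave-one-out
  panel moments; z-scores are combined over 7-bin windows by Stouffer's
  method, `Z = sum(z)/sqrt(w)`, and same-sign runs with `|Z| >= 3.5` become
  segments.
* **Screen rule** — a subject is *screen positive* iff any called segment
  is >= 15 Mb (prespecified, inclusive).
* **Catalog annotation** — each segment maps to the chromosome arms
  covering >= 25 % of it and is classified against a recurrent-CNV catalog:
  `q < 0.25 & frequency > 0.5` highly specific, `q < 0.25` moderately
  specific, otherwise non-specific.
* **Aneuploidy arm** — a simplified NIPT-style normalized-chromosome-value
  screen for chromosomes 13/18/21/X with no-call QC on normalizing
  chromosomes.
* **Evaluation** — sensitivity/specificity with exact Clopper–Pearson 95 %
  intervals, per-stage detection, per-arm tallies.
* **Synthetic cohorts** — a fully seeded generator (negative-binomial
  counts, per-sample GC bias, tumor-fraction-diluted truth profiles) for
  calibration, spike-recovery and dose-response studies.

See `vignettes/cfScreen-methods.Rmd` for the models, parameter choices and
known limitations.

## Worked example

The package ships the summary tables of a published 64-subject case/control
plasma screening cohort (32 HGSOC cases — 16 early, 16 advanced — and 32
benign controls) as plain-text fixtures, and recomputes every headline
number from them:

```r
library(cfScreen)
rep <- workedExampleReport()
```

```
sensitivity  40.6%  (95% CI 23.7-59.4)     # 13/32 cases screen positive
specificity  93.8%  (95% CI 79.2-99.2)     # 2/32 controls screen positive
   arm direction n
    8q      gain 7      # subjects among the 13 true positives with the event
    3q      gain 5
   13q      loss 4
   20q      gain 4
```

`rep$byStage` gives 6/16 early and 7/16 advanced cases detected, and
`rep$highlySpecificSubjects` shows 12 of the 13 true positives carry at
least one highly specific (catalog) CNV.

End-to-end on synthetic data — simulate a case, call it, screen it:

```r
genome <- defaultGenome()
grid   <- makeDefaultGrid(genome, 1e6)            # ~3,050 x 1 Mb bins
panel  <- preparePanel(simulatePanel(grid, 20, seed = 1))
index  <- buildReferenceIndex(panel, k = 100)

truth <- drawTumorProfile(defaultCatalog(), genome, tumorFraction = 0.2, seed = 7)
case  <- simulateCase(grid, truth, seed = 99)
res   <- callSample(case, index)
segs  <- annotateSegments(res$segments, genome, defaultCatalog())
applySizeRule(segs, "case_demo")
```

```
TruthProfile: tumor fraction 0.200, 20 events (17 arm-level, 3 focal)
ScreenCall 'case_demo': positive (55 segments, 19 >= 15.0 Mb)
 chrom    sizeMb direction arms           class
     5 130.91526      loss   5q highly_specific
     6 108.00000      loss   6q highly_specific
     4 103.00000      loss   4q highly_specific
     8  99.00000      gain   8q highly_specific
```

A screen-positive call with arm-level events matching the recurrent-HGSOC
catalog — exactly the signature the screen is designed to flag.
`plotZProfile(res$zprofile, "8", res$segments)` draws the individual
(blue) and windowed (red) z tracks with called segments underneath;
`writeSegments()` / `screenReport()` / `writeReport()` produce BED and
JSON outputs.

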