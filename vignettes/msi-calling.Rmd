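---
title: "Calling microsatellite instability from fragment peak tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling microsatellite instability from fragment peak tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msical)
```

## The measurement and its abstraction

A microsatellite marker amplified from tumour and matched normal tissue and
resolved by capillary gel electrophoresis yields, per sample, a set of
fragment peaks: a size in base pairs (fractional, since the instrument
interpolates against a ladder) and a signal in relative fluorescence units
(RFU). `msical` starts from that peak list — it does not do peak calling or
baseline subtraction from raw fluorescence, which the instrument software
already performs. The unit of comparison is the *trace*: all peaks for one
sample × marker × role (tumour or normal), gated to the marker's configured
size window and with same-size peaks merged.

A mismatch-repair-deficient tumour replicates microsatellites sloppily, so
its PCR products contain length alleles absent from the matched normal. The
caller's job is to find the signal those *novel* alleles carry, without
being fooled by two artifacts that affect both tissues equally: PCR stutter
(minor peaks one repeat unit below a true allele) and baseline noise peaks.

## The calling rules and their edge cases

A tumour peak is novel iff all three hold:

1. **Noise filter.** Its signal is at least `noise_fraction` (default 0.02)
   of the total tumour-trace signal. The threshold is computed against the
   *pre-filter* total, and the boundary is inclusive: a peak at exactly 2%
   survives. The stated filtering rule ("less than 2% removed") and the
   stated novelty rule ("more than 2% required") disagree at exactly 2%; we
   resolve this with a single coherent threshold — surviving the filter *is*
   the signal criterion — rather than a second strict re-test, and the value
   is configurable because noise floors are instrument- and
   laboratory-specific.
2. **Distance.** It lies at least `min_novel_distance_bp` (default 2,
   inclusive) from every peak of the matched normal. This is what absorbs
   stutter: a stutter peak of a shared allele sits one repeat unit (1–2 bp)
   from it and is vetoed by proximity, so stutter is handled implicitly
   rather than modelled.
3. **Extended range.** It lies no more than `max_outside_range_bp` (default
   10, inclusive) outside the full normal peak-size range. Peaks further out
   are treated as artifacts: they can never be novel, but in the default
   denominator mode they still count in the total signal, so they dilute
   rather than inflate the result.

Distances are computed on raw fractional sizes; nothing is rounded before
comparison. The normal trace is noise-filtered with the same threshold
before the distance and range computation (`filter_normal = TRUE`). The
sources are silent on this point; we filter symmetrically so that a normal
trace's own baseline noise cannot veto genuine novel peaks or stretch the
range, and the choice can be switched off. If the normal trace is empty
after preprocessing the marker is flagged missing (a QC failure, not an
error): FFPE dropout is routine and must not abort a run.

The marker's **allelic variability** is 100 × the summed signal proportion
of novel peaks. The proportion denominator is the pre-filter within-window
total by default (`denominator_mode = "pre"`); `"post"` divides by the
post-filter total instead. One consequence of the pre-filter mode worth
knowing: any single novel peak must carry ≥ 2% of signal to survive the
filter, so per-marker variabilities strictly between 0 and 2% are not
producible by the caller — reported values in that range can only arise
from rounding of a different internal pipeline, and the packaged validation
cohort indeed contains a few printed 1% entries.

## Classification

A marker is *unstable* when its variability strictly exceeds
`marker_instability_threshold_pct` (default 2%; the validation cohort's
printed rows with 2% cells count them stable, supporting the strict
inequality). Two sample-level systems are computed side by side:

* **NCI marker count**: MSS / MSI-L / MSI-H for 0 / 1 / ≥ 2 unstable
  markers.
* **MSI score**: the plain sum of the five variabilities (0–500). Tiers:
  MSS < 3, MSI-L on the closed interval [3, 5], MSI-H > 5. The boundary
  placement follows the validation cohort: every sample with score exactly
  5 is tiered MSI-L and the score-6 samples MSI-H; scores of 0 are MSS.
  For MSI-H samples the score is re-reported as the Toh score (total
  high-level MSI), quantifying the degree of instability.

Classification always operates on unrounded variabilities; reports display
integer percent (rounded half away from zero). The packaged cohort's
printed scores occasionally differ by one from the sum of their printed
integer variabilities — the signature of unrounded internal arithmetic —
so `msical` stores full precision in JSON reports and rounds only for
display. Missing markers propagate as NA: statuses are computed over the
available markers with a QC flag, and the score is a plain sum, not
rescaled to /500; that is conservative and transparent, but a user should
treat a 4-marker score near a tier boundary with suspicion.

## Concordance with immunohistochemistry

IHC detects loss of mismatch-repair protein expression and can only output
MSS or MSI-H. Concordance analysis therefore excludes samples the CGE
method calls MSI-L, then scores agreement on the remainder; percentages are
rounded to the nearest integer. `tier_counts()` reports how many samples
each method places in each tier, and `group_score_test()` compares MSI
scores across subgroups with a Kruskal–Wallis test (average ranks for
ties, chi-square approximation; `group_mean_test()` provides the two-group
Welch t-test). These delegate to the standard `stats` routines; the test
suite cross-checks the H statistic against a first-principles tie-corrected
rank computation.

```{r cohort}
cohort <- specimen_cohort()
res <- classify_variability(cohort)
concordance_table(res, cohort_ihc_labels(cohort))
```

## The synthetic electropherogram simulator

No raw instrument peak data are published for this assay, so the package
ships a generative stand-in that the whole test suite runs against. Per
marker it emulates:

* one or two germline alleles (`main_signal_rfu`, default 1000 RFU) with a
  geometric stutter ladder below each (`stutter_decay` default 0.15, one
  stutter position by default);
* multiplicative log-normal signal jitter (`signal_cv` default 0.05);
* Poisson-count baseline noise peaks (rate 2/trace) at uniform positions,
  with signals bounded at 1.5% of an allele peak — deliberately below the
  2% filter so that ground-truth variability stays closed-form;
* a tumour clone as a deterministic mixture: `(1 − f) ×` germline profile
  `+ f ×` shifted profile, where `f` is the tumour fraction and the shifted
  allele (default −3 bp) brings its own stutter ladder.

In the noiseless, stutter-free single-allele limit the expected variability
is exactly `100 f`, which the tests verify, and with the default stutter the
shifted allele of a mononucleotide marker carries about `0.87 f` of the
trace signal — above the 2% filter already at `f = 0.05`, which is why the
simulated dilution series is called MSI-H down to 5% tumour fraction. A −3
bp shift at a dinucleotide marker lands 1 bp from the normal allele's −2 bp
stutter and is vetoed by the distance rule until its own stutter clears the
filter at high fractions; we kept this configuration because it exercises
the proximity veto realistically and reproduces the per-marker dropout seen
in real dilution experiments.

All randomness flows from one integer seed, split per sample × marker ×
role by hashing the labels (`split_seed()`), so any single trace is
reproducible in isolation and outputs are byte-identical across runs.

What the simulator does **not** emulate: dye-mobility shifts, camera
saturation, size-calling error correlated across peaks, heteroduplex
artifacts, and real stutter's dependence on repeat length. Passing
recovery tests on simulated data therefore demonstrates the *algorithm's*
correctness under the stated noise model, not assay performance on any
particular instrument; thresholds should still be calibrated locally.

## Numerical and design choices

* Duplicate sizes within a trace are merged by summing signal; peaks are
  kept strictly ordered by size.
* Signal binds to peak height by default; a column mapping switches to area
  for instruments that export both.
* All inclusive/exclusive boundary choices are: noise filter ≥, novelty
  distance ≥ 2, extended range inclusive, marker instability strictly > 2%,
  MSI-L score tier closed [3, 5].
* Degenerate inputs: zero-total-signal traces filter to empty with a QC
  flag; an all-missing sample yields NA statuses rather than an error; a
  concordance evaluation with zero samples after MSI-L exclusion reports an
  undefined percentage.
* Reports are byte-stable; JSON serialises doubles at 17 significant digits
  so numeric fields round-trip exactly.

Test problem sizes: the novelty oracle comparison runs 1100 random
instances of up to 8 peaks per trace; the limit-of-detection study runs 20
seeds × 7 mixing fractions × 5 markers, sizes at which the full suite
completes in about a minute on a single core while leaving the stochastic
claims well-resolved.

## Limitations

* The caller presumes a matched normal; tumour-only calling (as in
  panel-of-normals NGS approaches) is out of scope.
* Variabilities below the noise threshold are unobservable by construction
  (see above), so very-low-level instability is indistinguishable from 0.
* The packaged validation cohort stores printed integer percentages; two of
  its rows carry unstable-marker counts inconsistent with a strict >2% rule
  on those integers (documented in the tests), a reminder that integer
  transcription loses the original precision.
* Marker windows, the five marker names, and all thresholds are
  configuration, but the score's /500 framing assumes exactly five markers.
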