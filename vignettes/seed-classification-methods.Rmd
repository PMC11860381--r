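---
title: "Methods: NIR seed classification by nested PLS-DA and hierarchical trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NIR seed classification by nested PLS-DA and hierarchical trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ryegrassNIR)
```

This vignette is the package's account of its science: the models and the
assumptions behind them, the tunable parameters and their defaults, what
the synthetic-spectra generator does and does not emulate, and the
numerical and design choices made where the workflow was genuinely open.

## The problem

A bag of perennial ryegrass seed carries two attributes of commercial
interest: its cultivar identity and whether the seed hosts a living
*Epichloë* endophyte (E+) or not (E−). Both are invisible to inspection.
Diffuse-reflectance FT-NIR spectroscopy of bulk seed (~10 g per scan)
probes overtone and combination vibrations of C–H, O–H and N–H bonds and
is sensitive to the compositional differences that track both attributes,
so a chemometric classifier over NIR absorbance spectra can screen seed
lots in seconds.

## Data model

Spectra live on a uniform, strictly descending wavenumber grid. The
acquisition axis spans 11,536–3952 cm⁻¹ with **949** digital points. Note
the arithmetic: a stated optical resolution of 16 cm⁻¹ together with 949
points over that range is only consistent with an **8 cm⁻¹ digital point
spacing** — the standard FT zero-filling convention of storing points at
half the optical resolution. The package fixes this spacing prominently in
`acquisition_grid()`; both printed point counts (949 over the full axis,
**632** after trimming to 9000–3952 cm⁻¹) follow exactly from
`(high − low)/spacing + 1`. Trimming removes the noisy high-wavenumber end
and is inclusive on both bounds (9000 cm⁻¹ lies on the grid and is kept).

Each scan carries metadata: `bag_id`, `cultivar` (Alto, Bronsyn, Maxsyn,
Trojan), `endophyte_strain` (twelve strains or `WE`, "without endophyte"),
`endophyte_status` (E+/E−) and `scan_index` (1–6). The container enforces
the invariant `strain == "WE"` ⇔ `status == "E-"`. CSV is the canonical
interchange format (metadata columns, then one column per wavenumber);
JCAMP-DX files (linear AFFN `XYDATA`/`XYPOINTS`) are read-only. The
proprietary binary instrument format is deliberately unsupported.

## Pre-treatment operators

Solid-sample NIR spectra mix chemical absorbance with physical artefacts:
multiplicative scatter (particle-size and path-length variation), additive
offsets, baseline tilt, and high-frequency noise. The package provides the
six standard corrections, each a row-wise linear operation:

| operator | what it removes | parameters (default) |
|---|---|---|
| `detrend` | tilted/curved baseline | polynomial order (1) |
| `snv` | offset + scale, reference-free | — |
| `msc` | offset + multiplicative scatter vs a reference | reference (calibration mean) |
| `emsc` | as MSC plus polynomial baseline | baseline order (2) |
| `savgol` | noise; forms derivatives | window 15, polyorder 2, deriv 0–2 |
| mean centre | column means | fitted on calibration |

Choices that were open and how they were resolved:

- **Detrend order** defaults to 1 (linear). The operator description in
  the chemometrics literature names the linear fit first, and the
  generator's tilt artefact is exactly linear; the order is configurable.
- **Savitzky–Golay derivatives are taken with respect to point index**,
  not cm⁻¹. On a uniform grid the two differ by the constant factor
  `(−spacing)^deriv`, which is irrelevant to classification after mean
  centering; callers who want physical units can rescale.
- **Edge handling**: at the spectrum ends the window shrinks to the
  available points and the local polynomial is refitted — no data are
  fabricated by padding, and output length equals input length. (This
  differs from implementations that slide a full-width, off-centre window
  at the edges; interior points agree to machine precision.)
- **MSC reference is the calibration-set column mean only**, never the
  pooled calibration+validation mean — the validation set must not leak
  into fitted state.

Pipelines (`preprocess_pipeline()`) apply steps in declared order;
state-bearing steps (MSC/EMSC reference, mean-centre means) fit on the
calibration data *as transformed by the preceding steps* and apply that
frozen state to any new data. The two optimized chains are
`cultivar_chain()` = Detrend → MSC-mean → SavGol(15, 2, 2) → mean centre
and `endophyte_chain()` = Detrend → SNV → SavGol(15, 2, 1) → mean centre,
with the order exactly as named (detrend first, mean centre last).

## Sample selection and outlier screening

**Kennard–Stone** picks the calibration set deterministically: the two
mutually farthest scans (Euclidean distance) seed the set, then each
addition maximizes its minimum distance to the scans already selected.
Ties (exact duplicates) break to the lowest index. The split is computed
on the *pre-processed* spectra — the same representation the classifier
sees — because the selection is part of the modelling workflow. The
default calibration fraction is 0.75.

**Venetian-blinds cross-validation** assigns the scan at position *i*
(0-based, in the dataset's recorded ordering) to fold
`floor(i / blind_width) mod n_splits`, defaults 10 splits and one sample
per blind. The generator randomizes scan order with a seeded shuffle so
the blinds interleave bags and classes reproducibly. Scans from one bag
may land in both calibration and validation; a bag-aware split would
change the question being asked (bag-level generalization) and is left to
the user.

**Q-residual screening** fits a rank-`k` PCA to the column-centered
matrix and takes each scan's squared reconstruction error. The threshold
default is the moment-matched scaled chi-square (`Q ~ g·χ²_h`,
`g = var(Q)/2·mean(Q)`, `h = 2·mean(Q)²/var(Q)`) at 99% confidence — the
standard approximation for squared PCA residuals. An empirical-percentile
threshold is available (`threshold_method = "percentile"`) but note that
by construction it flags the top `(1 − confidence)` fraction of scans
whether or not anything is wrong with them, which makes it unsuitable for
answering "are there any outliers?"; the chi-square rule is therefore the
default.

`screen_outliers()` packages the recommended procedure for raw spectra:
MSC against the mean spectrum, then detrend, then Q residuals at rank 6
(the number of absorption-band amplitude directions the simulated class
structure spans), with each scan's Q multiplied by its squared MSC slope.
That last step matters: MSC divides each scan by its fitted scatter
factor, so the corrected residual noise — and hence Q — of a strongly
scattering scan is inflated by a known per-scan constant. Rescaling by
the squared slope re-expresses all Q values in the raw-absorbance metric
and removes this spurious spread, which otherwise pushes legitimate
high-scatter scans toward the threshold. Screening in the
scatter-corrected domain (rather than on raw spectra) is also what keeps a
narrow spike's variance from being absorbed into the leading principal
components: the scatter directions dominate raw-domain variance, and once
they are removed the in-control model needs only the six amplitude
directions.

## PLS-DA

Binary classification is latent-variable regression: class membership is
coded +1 (the target class 1) and −1 (everything else, possibly several
pooled classes), both spectra and code are centered on the calibration
data, and NIPALS PLS1 extracts components (weight = covariance direction,
score, X-deflation) up to `n_lv`. The algorithm is deterministic and at
full rank reproduces the ordinary least-squares solution, which is how it
is tested. Calibration score vectors are mutually orthogonal by
construction.

**Decision threshold.** The continuous predicted response must be cut
into two classes. The toolbox convention this emulates is not publicly
specified, so the package default fits one normal density per class to the
calibration predictions and thresholds at the density crossing between
the class means (equal spreads reduce this to the midpoint of the means);
if no crossing lies between the means, or a class has fewer than two
predictions or zero spread, it falls back to the midpoint. A fixed
threshold of 0 (the midpoint of the ±1 codes) is selectable. A response
exactly at the threshold goes to class 1. The gaussian-crossing rule is an
approximation and is flagged as such.

**Metrics.** `class error = 1 − (sensitivity + specificity)/2`, equal to
the mean of the false-positive and false-negative rates; it is the
model-selection metric throughout because it is insensitive to class
imbalance. Every `overall accuracy` the package reports is defined as
`1 − class error` of the stated context — calibration, cross-validation
or prediction — and the context label always travels with the number.

**Cross-validation** refits the *entire* pipeline state (MSC reference,
means) and the PLS decomposition per fold, so no held-out scan influences
any fitted state; held-out predictions are pooled into one report.
Latent-variable selection scans 1..`max_lv` (one decomposition per fold
serves all counts), minimizes pooled CV class error, and breaks ties
toward fewer variables.

**Nested sequences.** Multiclass problems are decomposed into ordered
binary steps: model class A vs the pooled rest, remove A, repeat; the
final step is a plain two-class model. The default order for the four
cultivars is Maxsyn → Alto → Bronsyn → Trojan (most separable class
first). `order = "auto"` chooses greedily by lowest one-vs-rest CV class
error at each step, the recommended recipe when no order is known.

## Hierarchical trees and bag votes

A hierarchy node holds one binary model plus its own fitted pipeline;
class-1 scans exit to the class-1 branch (terminal label or subtree), the
rest continue. The cultivar tree chains the nested steps (depth 3, four
terminals); each cultivar also gets a single-rule endophyte tree
(terminals "Alto E+", "Alto E−", ...); `combine_trees()` grafts the
endophyte trees onto the cultivar terminals, giving eight class terminals.
The combined tree is *constructed* to agree with sequential application
of the two stages, and the tests verify that equivalence scan by scan.

The "otherwise" branch: a scan a node cannot process — a constant
spectrum rejected by SNV/MSC, a non-finite response — becomes
`Unclassified` rather than an exception. Out-of-distribution gating
(e.g. Q residuals at each node) is deliberately *not* applied by default:
failure-only semantics keep the tree a pure partition of processable
scans, and distributional gates belong in explicit screening before
classification.

Bag-level decisions vote over the six sub-sample scans: accept the most
frequent terminal label if it has at least 4 of 6 votes, else
`Inconclusive`. The conservative below-threshold outcome (no forced
assignment) is a quality-control posture: an inconclusive bag is rescanned
or genotyped, not guessed. With a scan error rate of a few percent and
errors independent across sub-samples, the vote converts, say, 95%
scan-level accuracy into >99% bag-level accuracy; the tests verify
bag ≥ scan accuracy on the benchmark.

## The synthetic-spectra generator

No raw spectra are deposited with the study this workflow reproduces, so
the generator is a first-class module that emulates the statistical
structure the analysis assumes:

- **Design**: `default_design()` reproduces the reference layout exactly
  — 135 bags (Alto 36, Bronsyn 32, Maxsyn 10, Trojan 57), 12 endophyte
  strains with the tabulated per-cultivar availability, endophyte-free
  bags 6/5/1/4, six scans per bag, 810 scan records, E+ in 714 of them.
- **Spectra**: six Gaussian absorption bands at 8230, 6824, 5736, 5176,
  4776 and 4304 cm⁻¹ (C–H 2nd overtone; N–H 1st overtone; S–H 1st
  overtone; O–H combination; C–H combination; C–H/CH₂ combination). Band
  amplitude = base + cultivar effect + endophyte effect + bag effect +
  within-bag jitter. The scan-level signal is then distorted by
  multiplicative scatter `(1 + a)`, additive offset `b`, linear tilt
  `t·ramp` and i.i.d. per-point noise — one artefact class per named
  pre-treatment, so unit tests can attribute each correction.
- **Outliers**: `inject_outliers()` adds a 5-point spike of 0.06
  absorbance (20× the per-point noise sd) to designated scans; the
  default scenario corrupts one Alto/NEA2 scan and two Alto/WE scans, so
  removal leaves 807 scans (Alto 213, E+ 713).

**Effect sizes are artifact choices, not reference values** — the study
reports no quantitative spectral effect for cultivar or endophyte. The
defaults are: cultivar effects of magnitude `3·noise_sd` with signed
per-cultivar patterns on the 8230 and 4776 cm⁻¹ bands; an endophyte
effect of `1.5·noise_sd` on the 6824 cm⁻¹ band (half the cultivar
magnitude, making endophyte status the harder task, as observed on real
data); `noise_sd = 0.003` absorbance. Band widths (sd 60–108 cm⁻¹, i.e.
FWHM ≈ 140–250 cm⁻¹) are typical of NIR overtone/combination features and
were chosen together with the within-bag jitter (`within_bag_sd = 0.002`)
so that scan-level cultivar accuracy lands in the low-to-mid 90s — the
range real-data models achieve — rather than at 100%, keeping the
majority-vote stage meaningful. Two modelling notes:

- **Within-bag jitter** (independent per-band amplitude noise per scan)
  represents sub-samples being different seeds from the same bag. It is
  the term that makes scan-level errors independent within a bag, which
  is precisely the regime where 4-of-6 voting adds value; without it,
  classification at these band signal-to-noise ratios is essentially
  perfect and the voting stage is vacuous.
- **Strain identity has no spectral effect** beyond E+/E− by default (the
  classifier targets status, not strain); per-strain jitter can be added
  via `cultivar_effect`/`endophyte_effect` overrides for robustness
  studies.

What the generator does **not** emulate: real covariance between
neighbouring wavenumbers beyond the band shapes, water-band interference
with temperature/humidity, harvest-year and storage effects, instrument
drift between sessions, and any nonlinearity of detector response.
Passing tests on synthetic data therefore demonstrate that the *pipeline
machinery* is correct and that the method recovers known structure at
realistic effect sizes; they do not certify real-data accuracy.

## The benchmark and problem sizes

`benchmark_suite(seed)` is the canonical scenario used by the tests and
the acceptance script: a 100-bag scaled-down design (Alto 27, Bronsyn 24,
Maxsyn 7, Trojan 42; 600 scans), default effect sizes, and documented
pass thresholds — scan-level cultivar accuracy ≥ 0.90 on held-out
validation scans and 4-of-6 bag-vote accuracy ≥ 0.98. `run_benchmark()`
executes trim → Kennard–Stone split → nested PLS-DA (10-fold
venetian-blinds CV, up to 8 latent variables per step) → tree assembly →
classification and voting; it reports scan accuracy on the 25% validation
scans and bag accuracy over all bags' six-scan votes. The 100-bag size
keeps a full end-to-end run at a few seconds on one core while leaving
every class with enough bags for stable CV; the outlier scenario runs on
the full 810-scan design because the three-in-810 detection problem is
the point of that test.

## Known limitations

- The Kennard–Stone representation is fitted on the pooled data before
  splitting (a representation choice, not model leakage); a raw-domain
  split option would avoid even that at the cost of splitting on
  uncorrected scatter.
- Class-1-side tie-breaking at the threshold and lowest-index
  tie-breaking in Kennard–Stone are conventions, chosen for determinism.
- The nested elimination order interacts with class imbalance: very small
  target classes (Maxsyn) show inflated balanced-error estimates in CV
  even when nearly all scans are correctly routed.
- JCAMP-DX support covers linear AFFN encodings only (no SQZ/DIF/DUP
  compression, no multi-block files).
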