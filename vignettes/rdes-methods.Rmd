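---
title: "Methods: the RDES format and the amplification-curve analyses behind it"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the RDES format and the amplification-curve analyses behind it}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdes)
```

## Why raw traces, not just Cq tables

A quantification cycle (Cq) and a PCR efficiency are summaries of an
amplification curve, produced by instrument software under settings the
reader of a paper cannot see. Two labs reporting the same Cq may have used
different baselines, different thresholds, and different efficiency
assumptions; the resulting target quantities can differ by severalfold,
and the error grows geometrically with Cq. The only way a reviewer can
check such results is to recompute them from the per-cycle fluorescence
readings. This package implements a complete path for that workflow: a
strict reader/writer/validator for the Real-time PCR Data Essential
Spreadsheet (RDES) layout — one row per well, annotation columns, then one
column per cycle — tools to reshape arbitrary instrument exports into it,
an interchange bridge to a subset of RDML (the XML exchange format for
real-time PCR runs), and a curve engine that re-derives baseline,
efficiency, Cq, and target quantities from the traces themselves.

## RDES reading and writing

The canonical serialization is fixed so that a plate has exactly one byte
representation: comma delimiter, dot decimals, header
`Well,Sample,Sample type,Target,Target type,Dye,Cq,1,2,...,N`, rows in
row-major well order (`A1..A12, B1, ...`) then by dye, unpadded well
labels, and empty cells (never `NA`/`NaN` text) for absent values. The
reader is deliberately more liberal, because real spreadsheets come out
of Excel in several locale conventions:

* **Delimiter** is auto-detected among comma, semicolon and tab; the
  choice is recorded in `meta$delimiter`. Decimal commas are accepted
  only when the field delimiter is semicolon or tab — with a comma
  delimiter they would be ambiguous.
* **Well labels** may be zero-padded on input (`A01`); they are
  normalized to `A1` and always written unpadded.
* **Missing Cq** is an empty cell. The placeholder strings `NA`, `NaN`
  and `Undetermined` are accepted on read with a warning, since several
  instrument exports emit them.
* **Elided columns.** Published excerpts of plates often omit interior
  cycles. A header cell containing an ellipsis between two integer cycle
  headers (`...,4,…,42,...`) is expanded to the full axis, with the
  elided readings stored as `NA`. This is how the package parses the
  twelve-well excerpt shipped in `inst/extdata/table1_rdes.csv`, whose
  header spans 45 cycles although only cycles 1–4 and 42–45 are printed.
* **Melt variant.** Column headers that are not consecutive integers
  starting at 1 (e.g. `60.0, 60.5, ...`) mark a melt table; the summary
  column is then `Tm` rather than `Cq`. We chose to mirror the Cq column
  with an optional Tm column because melt data belong in the same
  raw-data package and a per-well melting temperature is the analogous
  one-number summary; a melt table without a summary column is also
  accepted.
* **Vocabularies.** Sample types (`unkn/std/ntc/nac/ntp/nrt/pos/opt`)
  and target types (`toi/ref`) use RDML's controlled tokens, validated
  case-sensitively: a token the validator does not know is an error, not
  a silent coercion. Multiplexed wells are separate rows sharing a
  `well_id` with different dyes.

Validation never throws: it returns a report of coded errors, warnings
and suggestions, so journal-side tooling can show all findings at once.
One suggestion is scale-based: a plate with at least 20 distinct samples
and 20 distinct targets is the size at which public repositories accept
qPCR raw-data deposits, and the report says so (`GEO_DEPOSIT`).

## Reshaping instrument exports

`reshape_table()` maps wide or long exports onto RDES through a
declarative `shape_spec` (loadable from JSON or YAML), so common
instrument layouts are configuration, not code. Wide layouts identify
trace columns by explicit list, regex, or numeric-only headers; long
layouts name the cycle and fluorescence columns and are pivoted with
duplicate-reading detection. Every mandatory RDES field must be covered
by a column mapping or a constant, with one pragmatic default: when no
sample column exists, the well label stands in for the sample name (many
exports carry none), and the substitution is recorded in `meta`.

## The RDML bridge

`to_rdml()`/`from_rdml()` implement a minimal subset of the RDML 1.2
element vocabulary: `sample` and `target` dictionaries, `react` elements
addressed by plate position via `pcrFormat`, and per-target `data` blocks
holding `cq`, amplification points (`adp` with `cyc`/`fluor`) and melt
points (`mdp` with `tmp`/`fluor`). A reported melting temperature is
carried in a `meltTemp` element so that the melt variant's summary column
survives the round trip. Two RDES-specific constraints are enforced on
import: all reactions must share an identical cycle (and temperature)
list, because an RDES plate is a rectangular table by construction, and
every sample/target reference must resolve. Files that are ZIP containers
(RDML's on-disk convention) are detected by magic bytes; bare XML is
accepted too. Full RDML — thermal protocols, experimenters, digital PCR —
is out of scope; unknown content is skipped, never fatal.

## The curve engine

### Model and baseline

The engine treats a trace as
`F_c = b + P q_c / (q_c + 1)` with `q_c = N0 E^c`: exactly exponential
while `q_c` is small, saturating at plateau height `P`. The baseline `b`
is first estimated robustly: the pre-amplification segment is the longest
initial run of cycles whose straight-line slope stays statistically
indistinguishable from flat (t-statistic below 3), and `b` is the median
of that segment, with the scaled median absolute deviation as the noise
spread. At least 10 cycles are required; traces with missing readings are
refused.

### Efficiency

The efficiency estimator is a window-of-linearity fit with explicit
saturation handling:

1. A four-parameter sigmoid fit of the whole trace (`stats::nls` with
   the self-starting four-parameter logistic) supplies `b`, `P` and `E`
   whenever the trace genuinely plateaus and the fit converges to
   admissible values (`E` in (1.05, 2.5], midpoint at least two cycles
   before the last). For a saturating trace this is equivalent to the
   log-linear fit of the deskewed signal `y/(1 - y/P)` using every
   exponential-phase cycle, which is why its `E` is reported when
   available.
2. Independently, all runs of 4–6 consecutive cycles lying above the
   noise band (`b + k * noise_sd`, `k = 10` by default — a conservative
   multiplier, configurable) and below half the observed amplitude are
   scored by the r-squared of the deskewed log-linear regression; the
   best window (ties broken toward longer, then earlier) is reported
   with its r-squared, and flags `LOW_R2` (r² < 0.99) and
   `EFFICIENCY_OUT_OF_RANGE` (E outside (1.6, 2.2]) are derived from it.
3. For traces with no plateau — pure exponentials, where the sigmoid is
   unidentifiable — `E` is `10^slope` of the window regression after a
   closed-form baseline refinement: consecutive differences of
   `b + A E^c` are geometric and independent of `b`, so they identify
   `A` and `E` and hence the offset. The refinement is accepted only
   within two noise SDs of the robust initial baseline; beyond that the
   differences are noise-dominated and the robust estimate is kept.

On noiseless exponential input this pipeline reproduces `E`, `Cq` and
`N0` to near machine precision (the test suite asserts 1e-6 relative),
and on simulated plates with 1% multiplicative noise it recovers
per-well efficiencies within 0.05 and Cq within 0.5 cycles for at least
95% of wells — the tolerances the acceptance battery checks.

### Threshold and Cq

Because "where the threshold sits" is exactly the kind of invisible
instrument setting raw data disclosure is meant to expose, the threshold
policy is explicit. The default is a plate-level standard: 10% of the
median plateau height across amplifying wells, so every well on a plate
is quantified against the same Nq; fixed-fluorescence and
noise-SD-multiple policies are available. `cq_threshold` is the
fractional cycle where the baseline-subtracted trace first crosses Nq,
located by log-linear interpolation between the bracketing cycles
(exact for exponential growth). A threshold-free alternative,
`cq_sdm`, is the second-derivative maximum of the smoothed trace refined
by parabolic interpolation. Target quantities follow the closed form
`N0 = Nq / E^Cq`, so they are expressed in the same arbitrary
fluorescence units as Nq.

Smoothing, here and in the melt engine, is a Savitzky–Golay filter of
polynomial order 2 over a 5-point window: a local quadratic fit that
preserves peak and inflection positions of noiseless sigmoids to well
under 0.1 cycle (or °C) — an exponential is multiplied by a constant
factor, leaving log-slopes untouched — while attenuating point noise.

### The audit

`audit_reported_cq()` is the reviewer-facing integrity check: every
reported Cq is compared against the recomputed one (default tolerance
1.0 cycles — deliberately generous, since the instrument's own threshold
is unknown), and no-template controls with detected amplification are
flagged as possible contamination.

## Quantification

Assay-specific efficiency is the mean of per-well efficiencies for a
target, excluding flagged wells, and requires at least two usable wells —
one well gives no handle on spread. Normalized expression divides each
target-of-interest quantity by the geometric mean of the reference-target
quantities of the same sample; geometric, because quantities are
ratio-scale and the aggregate must not depend on the order or units of
the references (an arithmetic mean would). Replicate wells are likewise
combined geometrically. Fold-differences are expressed against a
calibrator sample, by default the first sample in plate order (logged in
the result). Any number of reference genes ≥ 1 is accepted.

`cq_bias_assessment()` tabulates the factor `(E_assumed / E_true)^Cq` —
the systematic error committed by computing quantities with the wrong
efficiency. Its log is linear in Cq, which is the quantitative core of
the argument for disclosing raw data: at `E_true = 1.9` assumed to be
2.0, the error is already ~4.7-fold at Cq 30.

## Melt analysis

The derivative engine computes −dF/dT of the smoothed trace (central
differences, one-sided at the ends). Peaks are local maxima with
topographic prominence of at least 5% of the curve's global maximum
(configurable), refined by parabolic interpolation; more than one peak
flags `MULTIPLE_PEAKS` (a primer-dimer indicator), none flags `NO_PEAK`.
Numerically flat derivatives (constant traces) short-circuit to
`NO_PEAK` rather than chasing floating-point ripple.

## The simulator

`simulate_amplification()` generates plates from the same saturating
model the engine assumes, with recorded ground truth — it stands in for
instrument data in every end-to-end test. Defaults describe a routine
96-well SYBR run: 8 samples × 12 targets, 45 cycles, per-target
efficiency drawn from U(1.8, 2.0), initial quantities log-uniform over
four decades (giving Cq roughly 17–31), baseline 1.2–1.6 a.u., plateau
10 a.u., 1% multiplicative noise plus 0.01 a.u. additive baseline noise,
and one reference target. The emitted Cq column is the generator's own
closed-form threshold crossing at 10% of plateau. Readings are rounded
to 4 decimals, as instrument exports are, which also makes the canonical
CSV byte-identical across runs with the same seed. `simulate_melt()`
sums logistic melting transitions (default width 0.8 °C, amplitude
5 a.u.) over a 60–95 °C grid in 0.5 °C steps.

What the simulator does **not** emulate — and hence what passing tests do
not establish about real data: inhibitor kinetics and cycle-dependent
efficiency decay, probe chemistries other than intercalating dyes,
baseline drift, plate-position and inter-plate batch effects, and
pipetting-volume variation between replicates. Results on simulated
plates validate the algorithms' correctness under their stated model,
not instrument behavior.

The shipped fixture `table1_infilled_synthetic.csv` deserves the same
caveat: the published excerpt prints only cycles 1–4 and 42–45, so
`infill_elided()` fills the interior with a deterministic model curve
anchored to the printed cells and the reported Cq (assuming E = 1.9).
It exists so end-to-end demonstrations can run on the excerpt; it is
synthetic in-fill, not reconstructed data, and parser-level tests use
only the printed cells.

## Problem sizes and numerical choices

The test suite and the acceptance script use: a 100-well plate (10×10)
at 1% CV for parameter recovery; 50 seeded 6-well plates for
serialization and RDML round-trip stability; 8 noiseless wells for melt
recovery; noiseless 30–40-cycle exponentials for the closed-form checks.
These sizes were chosen to exercise every code path at plate scale while
keeping a full run near interactive speed. Ties in window selection are
resolved within an r² tolerance of 1e-9 (longer window, then earlier
start); flat-derivative detection uses an absolute 1e-10 band; canonical
numeric serialization uses `%.15g`, which round-trips instrument-style
decimals exactly.

## Known limitations

* The efficiency estimator assumes a single logistic-saturating phase;
  bi-phasic or inhibited curves will fit poorly and should be caught by
  `LOW_R2`/`EFFICIENCY_OUT_OF_RANGE` flags, not silently quantified.
* The RDML bridge covers the subset needed for raw-data disclosure, not
  the full schema; documents relying on per-reaction cycle lists that
  differ across reactions are rejected by design.
* Equivalence with any specific published curve-fitting package's
  numerics is not claimed; the estimator here is defined by the
  closed-form and recovery properties its tests assert.
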