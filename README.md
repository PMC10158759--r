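# rdes

Tools for disclosing and auditing raw RT-qPCR data in the **Real-time PCR
Data Essential Spreadsheet (RDES)** format.

Most published RT-qPCR results are reported only as quantification cycles
(Cq) and, sometimes, PCR efficiencies — summaries produced by instrument
software under baseline and threshold settings the reader cannot see.
Ignoring the assay-specific efficiency, or setting thresholds
inconsistently, biases target quantities by a factor
(E<sub>assumed</sub>/E<sub>true</sub>)<sup>Cq</sup> that grows
geometrically with Cq. The remedy is to publish the per-cycle fluorescence
readings themselves, in a layout simple enough to go into a supplementary
CSV: one row per well with annotation columns
(`Well, Sample, Sample type, Target, Target type, Dye`), a `Cq` column,
and one column per cycle. This package is the tooling around that layout,
for authors preparing submissions and for reviewers and editors checking
them:

* **rdes_io** — strict reading, canonical (byte-deterministic) writing,
  and rule-based validation of RDES tables, amplification and melt
  variants, including published excerpts with elided cycle columns;
* **tableshaper** — declarative reshaping of arbitrary wide/long
  instrument exports into RDES;
* **rdml_bridge** — lossless interchange with a subset of RDML 1.2, the
  XML exchange format for real-time PCR runs (ZIP containers included);
* **curve_engine** — recomputation, from the raw traces, of everything a
  Cq table hides: baseline, window-of-linearity PCR efficiency E,
  threshold and second-derivative-maximum Cq, and target quantity
  N0 = Nq / E<sup>Cq</sup>, plus an audit comparing reported against
  recomputed Cq and flagging amplifying no-template controls;
* **quantify** — efficiency-corrected normalized expression against the
  geometric mean of reference genes, fold-differences against a
  calibrator, and the Cq-dependent bias curve;
* **melt_engine** — −dF/dT derivative curves and Tm peak calls with
  primer-dimer (multiple-peak) flags;
* **synth** — a simulator of amplification and melt plates with recorded
  ground truth, used by every end-to-end test;
* a command-line entry point (`exec/rdes`) wiring it all together:
  `validate | reshape | convert | analyze | quantify | melt | simulate`.

## Worked example

The package ships the twelve-well excerpt of a published RDES plate
(`inst/extdata/table1_rdes.csv`; cycles 5–41 are elided in print, and the
reader reconstructs the 45-cycle axis from the header):

```r
library(rdes)
plate <- read_rdes(system.file("extdata", "table1_rdes.csv", package = "rdes"))
validate_plate(plate)
#> <validation_report: 0 error(s), 1 warning(s), 0 suggestion(s)>
#>   W MISSING_TRACE_VALUES: 444 trace reading(s) absent (elided or empty cells)
#>   counts: n_wells=12 n_samples=12 n_targets=2 n_cycles=45
```

Zero errors: the excerpt is valid RDES. The 444 missing readings are the
elided cycles (12 wells × 37 cycles). A synthetically in-filled companion
fixture (`table1_infilled_synthetic.csv`, deterministic model in-fill of
the elided cells — see the methods vignette) lets the curve engine run end
to end:

```r
filled <- read_rdes(system.file("extdata", "table1_infilled_synthetic.csv",
                                package = "rdes"))
fits <- analyze_plate(filled)
fits[c(1, 12), c("well_id","sample","reported_cq","cq_threshold","efficiency_E","r2")]
#>    well_id   sample reported_cq cq_threshold efficiency_E r2
#> 1       A1 Embryo_1        33.2        33.25          1.9  1
#> 12     H12 Adult_12        19.0        18.87          1.9  1
attr(fits, "nq")
#> [1] 1.460
audit_reported_cq(filled)   # 0 warnings: reported Cq agree with the traces
```

The recomputed Cq (threshold: 10% of the plate's median plateau,
Nq = 1.46 a.u.) reproduce the reported column to within a fraction of a
cycle, and the fitted efficiency is 1.9 per cycle. And this is why the
efficiency must travel with the data — assuming perfect doubling (E = 2)
when the assay actually runs at 1.9 inflates quantities by:

```r
cq_bias_assessment(1.9, 2.0, c(20, 35), by = 5)
#>   cq fold_error
#> 1 20       2.79
#> 2 25       3.61
#> 3 30       4.66
#> 4 35       6.02
```

— almost fivefold at Cq 30.

From the shell, the same audit pipeline is:

```sh
rdes simulate --samples 8 --targets 12 --seed 1 -o plate.csv --truth truth.json
rdes validate plate.csv
rdes analyze plate.csv -o fits.json
rdes quantify fits.json -o quant.csv
rdes convert plate.csv -o plate.rdml     # and back: rdes convert plate.rdml -o back.csv
```

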