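# fireepi

Care-episode analytics for fire-related injuries in hospital-discharge
registers.

National discharge registers record one row per inpatient discharge, so a
single burn injury appears as a chain of transfer records and, often, as
repeat admissions over the following years. `fireepi` is for injury
epidemiologists and register analysts who need to turn such extracts into
injury-level statistics while controlling three well-known data-quality
problems: incomplete external-cause (E-code) recording, the absence of a
"first admission" marker, and the ambiguity of which inpatient days an
injury should be charged with.

## What the package computes

* **Care episodes.** Records chain into episodes when the next admission
  follows the latest discharge by at most *g* days (default *g* = 2,
  inclusive); chaining runs through the running maximum discharge, so it
  equals merging record intervals extended by the tolerance. Bed days use
  the half-open union convention: an episode's days are
  `|union of [admission_i, discharge_i)|`, same-day stays counting 1.
* **Mechanism of injury** per episode, with strict precedence over
  evidence from any record: FIRE (E-code in X00–X09, X76, X97, Y26;
  ICD-9 E890–E899) > BURN (N-code in T20–T32, T95; ICD-9 940–949) >
  GAS (T58–T59; ICD-9 986) > OTHER. Plus detectors for contradicting
  E-codes inside fire episodes and for inpatient-onset (typically
  psychiatric) injuries.
* **E-coding completeness** by year and provider type, at record level
  (missing vs unspecific X58/X59 among burn/gas-main records) and at
  episode level (IDENTIFIED / UNSPECIFIC_ONLY / ALL_MISSING).
* **Clearance period** separating readmissions from new incident
  injuries: for backward recurrence times *t* (gap from a person's
  previous burn episode), the hazard is estimated as a kernel-smoothed
  Nelson–Aalen (Ramlau–Hansen) estimator

  `h(t) = (1/b) * sum_i K((t − t_i)/b) * d_i / Y(t_i)`

  with Epanechnikov kernel *K*, bandwidth *b* = 0.5 y, reflection at 0,
  and right-censored tail gaps in the risk set *Y*. The clearance period
  is the time at which `h(t)` enters a ±25% band (widened by 2 pointwise
  SEs) around its long-run level and stays there. Incidence can then be
  counted under a first-episode-only or a clearance-window definition.
* **Bed-day inclusion criteria** A–E (exclude psychiatry; exclude
  long-term care; injury diagnosis among first three N-codes; injury main
  diagnosis; fire E-code present) as yearly percentages of the
  unrestricted total.
* **Synthetic registers** with full ground truth (true episodes,
  mechanisms, deleted E-codes, readmission changepoint) for validating
  every stage, since real national registers are confidential.

## Worked example

```r
library(fireepi)
sim <- generate_register(register_config(seed = 1))
run <- run_pipeline(sim$records, output_dir = "fireepi_out")
print(run)
```

```
fireepi pipeline run
  14955 records -> 13496 care episodes
 category records episodes identified_share_pct
    TOTAL   14955    13496                   NA
     FIRE    1276      936                   18
     BURN    4992     3950                   77
      GAS     322      248                    5
    OTHER    8365     8362                   NA
  clearance period: 2.30 y (capture 95.7%)
  contradicting fire episodes: 17; inpatient-onset flags: 5
```

The partition table mirrors the register convention: counts of records
and episodes per mechanism, and each identified mechanism's
integer-rounded share of the fire + burn + gas episodes. Here 18/77/5
is the *classified* partition — the generator's true mechanism mix is
21/74/5, and the gap is exactly the effect of year-dependent E-code
missingness pushing fire episodes into the burn class, which is the
phenomenon the completeness audit quantifies.

```r
summary(run$clearance)
```

```
Clearance-period estimate from backward recurrence times
  sample: 4181 readmission gaps, 704 censored tails, horizon 14.2 y
  smoothing: Epanechnikov bandwidth 0.50 y, grid step 0.05 y
  plateau band: +/-25% of long-run hazard 0.151 /y
  clearance period: 2.30 y (stabilised)
  capture fraction: 95.7% at clearance, 95.4% at 2 y
```

The register was generated with a readmission changepoint at 2 years;
the estimate lands at 2.30 y (kernel smoothing biases the entry point
about half a bandwidth rightward), and a 2-year clearance rule would
capture 95% of within-10-year readmission gaps.
`truth_check(sim, run$records, run$mechanisms, clearance = run$clearance)`
scores the run against the generator's ground truth: 100% episode
recovery and a mechanism confusion matrix whose only off-diagonal mass is
FIRE episodes degraded by deleted E-codes.

All outputs are also written as CSV (episode file, partition summary,
completeness tables, episode-completeness by year, hazard curve,
clearance summary, incidence counts, criteria report, contradiction and
inpatient-onset listings) together with a `manifest.json` echoing every
parameter. A thin command-line wrapper with the same stages as
subcommands lives at `inst/scripts/fireepi.R`:

```sh
Rscript inst/scripts/fireepi.R generate --n-persons 2000 --seed 1 --out register.csv
Rscript inst/scripts/fireepi.R all --input register.csv --out-dir out/
```

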