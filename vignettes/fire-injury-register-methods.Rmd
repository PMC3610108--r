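---
title: "Methods: care-episode analytics for fire-related injuries in discharge registers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: care-episode analytics for fire-related injuries in discharge registers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fireepi)
```

## The problem

National hospital-discharge registers record one row per inpatient
discharge, not one row per injury. A single burn injury typically produces
several rows — transfers between wards, hospitals and specialties each
yield their own record — and severe burns produce repeat admissions for
years. Three practical obstacles follow for anyone studying fire-related
injuries (exposure to smoke, fire and flames, burns, and combustion gas
poisonings) in such data:

1. **External-cause (E-code) completeness.** The mechanism of injury lives
   in the E-code, which historically was often missing — especially in the
   first years after the ICD-10 transition — or recorded only as the
   uninformative X58/X59 ("accidental exposure to other and unspecified
   factors").
2. **Incidence vs. readmission.** Registers carry no field marking "first
   admission for this injury", so incident injuries must be separated from
   readmissions by a rule.
3. **Attributable inpatient days.** Which records of an episode count as
   injury care is ambiguous: psychiatric stays, long-term-care decisions
   and complication admissions (pneumonia, urinary tract infection, ...)
   can inflate or deflate totals depending on the inclusion rule.

`fireepi` implements a complete, tested pipeline for these three problems,
plus a synthetic register generator that provides ground truth for every
stage. Because real national registers are confidential, the package's
validation rests on worked examples with published summary numbers and on
parameter-recovery experiments against the generator.

## Care-episode construction

Records are chained per person into *care episodes*: a record joins the
running episode when its admission date is at most `gap_days` (default 2)
days after the latest discharge date seen so far in that episode. The
running-maximum formulation makes chaining transitive and handles
overlapping records (day surgery during a ward stay) naturally; it is
equivalent to merging the record intervals after extending each by the
tolerance, and the test suite verifies this equivalence against a
brute-force transitive-closure oracle on randomised histories.

Ties on admission date are broken by discharge date *descending*, so the
longest stay leads the episode; the "first record of the episode" used by
the inpatient-onset detector is then the substantive ward record rather
than a same-day side procedure.

**Bed days** use the half-open convention `[admission, discharge)`: a
record contributes `discharge − admission` days, a same-day stay counts as
one day, and an episode's total is the union of its records' day sets so
transfer overlap is never double-counted. Registers differ in their
day-counting conventions; the half-open union is the standard choice and
is applied uniformly. Annual totals attribute all of an episode's days to
the calendar year of the episode's first admission (incidence framing); a
day-splitting attribution would change year boundaries only for episodes
spanning New Year.

## Code sets and matching

All code groups are parsed from compact range specifications
(`"X00-X09,X76,X97,Y26"`) into sets of three-character ICD-10 category
stubs; recorded codes are uppercased, dot-stripped and matched on their
category stub, because registers append subcategory digits with or without
dots. ICD-9 codes are numeric with an optional `E` prefix for external
causes; numeric N-codes match on a configurable prefix length (default 3,
so the burn range 9400–9490 becomes the stubs 940–949) and `986` (carbon
monoxide) matches exactly at three digits. The ICD-9 E-code domain is
E880–E900; whether E900 (heat) was meant inclusively is ambiguous in the
register documentation, so the bound is a `code_catalog()` argument,
inclusive by default.

The burn diagnosis set includes the sequelae code T95 alongside the acute
range T20–T32. T95 admissions are genuine burn care and are therefore
also part of the backward-time sample below; excluding them is possible by
overriding `BURN_N` via `read_code_config()`.

## Mechanism classification

Episodes are classified with a strict precedence using evidence from
*any* record of the episode:

* **FIRE** — any record carries a fire-related E-code
  (X00–X09, X76, X97, Y26; ICD-9 E890–E899);
* **BURN** — otherwise, any record carries a burn N-code (T20–T32, T95;
  ICD-9 940–949) in any diagnosis position;
* **GAS** — otherwise, any record carries a combustion-gas N-code
  (T58–T59; ICD-9 986);
* **OTHER** — none of the above.

Episode-level evidence is deliberate: an episode whose first record lost
its E-code is still identified by a later coded record, which makes the
classification much less sensitive to missingness than record-wise
inspection. The accidental gas-exposure E-code X47 contributes *gas*
evidence by default (`gas_ecode_evidence = TRUE`), since the mechanism
partition defines the gas group by diagnosis; the switch exists because
X47 is also a plausible fire-adjacent candidate code.

Two data-quality detectors accompany the classification. Fire episodes
containing records whose E-code belongs to the contradicting ranges
(X10–X19 heat contact, X30–X39 forces of nature, W32–W40
firearms/explosions, W85–W99 electricity/radiation/ambient extremes) are
*reported*, never excluded — differing codes may describe one event more
richly than a single code could, and coding noise is expected. And for
each person's first fire episode, a first record with no fire, burn or
gas evidence at all suggests the injury occurred during an ongoing stay
(inpatient onset); the detector reports whether that record's main
diagnosis is psychiatric (F00–F99) and whether its specialty field is
psychiatric care.

## E-coding completeness

Record-level completeness is audited among records whose *main* diagnosis
is a burn or a combustion gas poisoning, stratified by admission year
and/or provider type: the share with a missing E-code and the share with
only X58/X59. Episode-level completeness classifies episodes as
IDENTIFIED, UNSPECIFIC_ONLY (at least one E-code present, all present
ones X58/X59) or ALL_MISSING. A present E-code outside the era's declared
domain (ICD-10 V01–Y89, ICD-9 E880–E900) still counts as specific —
completeness is about the presence of any external-cause information —
but is warned about. Percentages are rounded to one decimal in
completeness tables and to integers in the partition summary; `share_pct()`
is the single rounding utility, so every table reproduces from raw counts.

## Clearance period from backward recurrence times

For every burn-diagnosis episode (mechanism FIRE or BURN) after a
person's first, the *backward time* is the gap from the previous
episode's end to this episode's start, in years. End-to-start anchoring
is the default because a readmission's proximity is to the end of prior
care; start-to-start anchoring can be had by passing episode starts as
ends. The population hazard of these gaps is elevated while readmissions
for the same injury dominate and settles to a roughly constant level once
genuinely new injuries take over. The *clearance period* is the time at
which the hazard enters that plateau: admissions closer than this to a
prior episode should be treated as readmissions when counting incidence.

The estimator is a Ramlau–Hansen-type kernel-smoothed Nelson–Aalen
hazard:

* Gaps from each person's last qualifying episode to the end of follow-up
  enter as right-censored observations. Without them the observed gaps
  are right-truncated and the hazard is biased upward at long backward
  times.
* Nelson–Aalen increments `d_i / Y(t_i)` are smoothed with an
  Epanechnikov kernel (default bandwidth 0.5 y on a 0.05 y grid), with
  reflection at zero as boundary correction.
* The grid's upper end defaults to the 95th percentile of all observed
  times: beyond that the shrinking risk set makes raw increments too
  unstable to smooth usefully (the same guard standard kernel-hazard
  software applies).

**Plateau rule.** The long-run level is the mean smoothed hazard over the
final third of the grid, and the clearance period is the smallest grid
time from which the hazard stays within ±25% of that level for the rest
of the grid. The band is additionally widened pointwise by two standard
errors of the smoothed hazard (computed from the kernel-squared increment
variances). This matters at realistic sample sizes: with a plateau hazard
of ~0.1/y and a few thousand gaps, the pointwise sampling SD in the
plateau region is ~20% of the level, so a fixed ±25% band is broken
somewhere along the tail in a large fraction of datasets even when the
hazard is genuinely flat. The SE-widened band is the same rule with its
noise accounted for, and it converges to the plain relative band as the
sample grows. If the hazard never enters the band, the grid maximum is
returned with `stabilised = FALSE`. All parameters (`band`,
`ref_fraction`, `z_se`, bandwidth, grid) are arguments and are reported
in the output.

The `capture_fraction` reports the share of within-horizon (at most 10 y)
readmission gaps at or below a given clearance period — the share of
obvious readmissions the rule would catch. `incident_episodes()` applies
either definition of incidence: `FIRST_ONLY` (each person's first
qualifying episode; the conservative bound on incidence) or `CLEARANCE`
(an episode is incident when no prior qualifying episode ended within the
clearance period before its start); the clearance count is provably at
least the first-only count.

The smoothing bias of the estimated changepoint is about half a
bandwidth to the right (the kernel window must clear the changepoint
before the estimate can enter the band), which is within the tolerance
used by the validation suite (bandwidth + 2 grid steps).

## Bed-day inclusion criteria

For fire episodes only, yearly bed-day totals are computed unrestricted
and under five record-level criteria: **A** psychiatric-specialty records
excluded; **B** long-term-care records excluded; **C** only records with
an injury diagnosis (S00–T98; ICD-9 default 800–999) among the first
three N-codes; **D** only records whose *main* diagnosis is an injury;
**E** only records with a fire-related E-code. Records failing the
criterion are removed *before* the union-of-days computation, so
percentages are comparable across criteria. Criterion D implies C
record-wise, hence D's totals never exceed C's; criterion E cannot match
a missing E-code, which is exactly the mechanism that makes E-code-only
day counting a serious underestimate. Each year's criterion total is
reported as a percentage of that year's unrestricted total, alongside the
median full-episode length.

## The synthetic register generator

`generate_register()` emulates the structures the analysis assumes — it
is a test harness, not a demographic model. Per person and year an injury
occurs with probability `injury_rate`; each injury spawns an episode of
`1 + Geometric(transfer_geometric_p)` records (capped at 6) with
inter-record gaps drawn from `gap_days_distribution` and log-normal
record stays; readmission episodes follow at gaps drawn from a
piecewise-constant hazard (`h1` before the changepoint `tau`, `h0`
after), the simplest structure consistent with an elevated-then-flat
backward-time hazard. Mechanism-appropriate N- and E-codes are assigned,
then E-codes are deleted with year- and provider-dependent probability or
replaced by X58/X59. Psychiatric records precede a share of incident fire
episodes (inpatient onset) and follow another share (aftercare);
secondary records of some fire episodes receive a contradicting E-code;
background non-injury episodes and long-term-care flags complete the
picture.

Defaults, chosen once as the package's study conditions:

| parameter | default | rationale |
|---|---|---|
| `n_persons`, window | 2000, 1996–2009 | an enriched injured cohort over a 14-year ICD-10 window |
| `injury_rate` | 0.03 /person-year | cohort enriched for injuries; yields ~800 injuries per register |
| `mechanism_mix` | 0.21 / 0.74 / 0.05 | the identified-mechanism episode partition reported for this setting |
| `transfer_geometric_p` | 0.8 | ≈1.25 records per episode, the records:episodes ratio registers show |
| stays | log-normal, median 5 d | median fire-episode lengths of 4–6 days |
| readmission `h1, h0, tau` | 1.0/y, 0.1/y, 2 y | readmission risk clearly elevated for ~2 years, then roughly constant |
| `ecode_missing_rate` | 0.65 → 0.02 by year | the published post-ICD-10 decline in burn-record E-code missingness |
| `ecode_unspecific_rate` | 0.02 → 0.11 by year | the concurrent rise of X58/X59 coding |
| provider mix / multipliers | 0.4/0.4/0.2, ×0.6/1.3/1.2 | university hospitals code best; multipliers have mix-weighted mean 1 so yearly marginal rates equal the configured rates |
| `psych_onset_rate` | 0.03 | ~3% of fire patients show inpatient-onset patterns |
| `contradiction_rate` | 0.035 | 2–5% of fire episodes carry contradicting codes |
| `complication_rate` | 0.15 | transfer/readmission records with a complication main diagnosis, so criteria C and D differ |
| `background_care_rate` | 0.3 /person-year | unrelated episodes so the OTHER class dominates, as in real registers |

Two bookkeeping details make the ground truth exact. Intended episodes of
one person whose intervals fall within the 2-day chaining tolerance of
each other are *merged in the truth* (mechanism by FIRE > BURN > GAS
precedence, incident if any member is incident): the emitted records
genuinely encode one episode, so the truth says so. And with the default
gap distribution (≤ 2 days) episode recovery by `assign_episodes()` is
then exact by construction; widening the gap distribution beyond the
tolerance degrades recovery by exactly the share of true episodes whose
records no longer chain, which the test suite verifies.

What the generator does **not** emulate: age/sex structure, mortality,
outpatient care, seasonal patterns, hospital-level clustering, or coding
practices beyond the modelled missing/unspecific/contradiction processes.
Passing tests therefore demonstrate that the pipeline's logic is correct
under the assumed structures — not that real-register estimates are
unbiased in the presence of structures outside the model.

## Numerical choices and degenerate inputs

* Empty record subsets have zero bed days; any non-empty subset has at
  least one (the same-day rule).
* `build_episodes()` on an empty frame returns an empty list; mixed
  person identifiers are an error, not a silent group-by.
* `smoothed_hazard()` refuses empty samples and non-positive bandwidths;
  a single duplicated duration with a tiny bandwidth produces the
  expected spike at the atom.
* Strata with no records produce `NA` percentages, never 0.
* All randomness in the generator flows from one seed; the same
  configuration is byte-identical on disk across runs.
* Validation problem sizes: the episode-construction oracle runs on 1000
  randomised person histories; clearance recovery uses 100 registers of
  2000 persons (about 4000 readmission gaps each); completeness recovery
  uses one 2000-person register. These sizes give the recovery checks
  comfortable binomial margins while keeping the full suite around a
  minute of compute.

## Known limitations

* The clearance estimate inherits the smoothing bias of kernel hazard
  estimation near a sharp changepoint (~half a bandwidth rightward);
  formal changepoint inference is out of scope.
* Backward-time sampling treats each gap as an independent observation;
  persons contribute multiple gaps, so standard errors computed from the
  gap count are slightly optimistic.
* ICD-9-era support covers the code sets needed for history monitoring
  (fire E-codes, burn and gas N-codes, injury range), not a general
  ICD-9 dialect.
* Incident classification under `CLEARANCE` cannot distinguish a genuine
  new injury occurring shortly after an old one from a readmission — by
  construction, no register rule can.

## A worked run

```{r example, eval = FALSE}
sim <- generate_register(register_config(seed = 1))
run <- run_pipeline(sim$records, output_dir = "fireepi_out")
print(run)
summary(run$clearance)
plot(run$clearance)
truth_check(sim, run$records, run$mechanisms, clearance = run$clearance)
```
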