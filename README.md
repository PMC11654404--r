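# palliaudit

Clinical audit of health-insurance claims filed under a catch-all
**"palliative chemotherapy — unlisted regimen"** benefits package for
breast cancer.

Public health insurance schemes reimburse hospitals through predefined
benefits packages. The unlisted palliative chemotherapy package is intended
for chemotherapy given to patients with *metastatic* disease, but it
accepts any regimen and so is easy to select inappropriately — for
example, for adjuvant (curative-intent, post-surgical) chemotherapy.
`palliaudit` is for health-services researchers and scheme regulators who
want to audit such claims reproducibly: it encodes a guideline-derived
decision sequence as a deterministic rule engine and ships everything
needed to run it end to end without confidential scheme data.

## The audit algorithm

Each claim record carries document-presence flags and a clinical abstract.
The engine applies fixed-order, first-match rules; the first rule that
fires assigns a single reason code whose prefix pins the package-selection
determination (`CA_*` cannot assess, `IN_*` inappropriate, `AP_*`
appropriate):

| # | check | reason when it fires |
|---|-------|----------------------|
| 1 | biopsy/FNAC report missing | `CA_NO_BIOPSY` |
| 2 | consent-form regimen ≠ clinical-notes regimen | `CA_REGIMEN_DISCREPANCY` |
| 3 | biopsy shows non-breast or variant condition | `IN_NON_BREAST_DX` |
| 4 | no metastasis documentation, no surgery date | `CA_NO_MET_NO_GAP` |
| 5 | no metastasis documentation, chemo ≤ 6 months after surgery | `IN_NO_MET_WITHIN_6MO` |
| 6 | only non-chemotherapy drugs | `IN_NON_CHEMO_DRUGS` |
| 7 | regimen has a first-line palliative role | `AP_FIRST_LINE` |
| 8 | regimen has a second-line palliative role | `AP_SECOND_LINE_{WITH,NO}_FIRST_DOC` |
| 9 | chemotherapy with no palliative role | `IN_NO_PALLIATIVE_ROLE` |

The *palliative context* behind rules 4–5 is established by documented
metastasis or by a surgery-to-chemotherapy gap of **more than six calendar
months** (strict, end-of-month clamped: `2019-08-31 + 6m = 2020-02-29`).
Treatment is judged appropriate for first-line therapy and for second-line
therapy with documented prior first-line; inappropriate when rule 9 fires
or an expert-review override flag is set; otherwise it cannot be assessed.
Drug names never appear in the rules — a YAML catalog maps drugs and named
combinations to guideline roles, and only the roles matter.

## Worked example

```r
library(palliaudit)

fixture <- build_table2_fixture()          # deterministic 50-claim cohort
results <- audit_cohort(fixture, load_catalog())
summarize_audit(results, fixture)
```

```
Audit summary: 50 claims (25 public, 25 private)

Package selection:
 package_determination count_both count_public count_private
           appropriate         15           11             4
         inappropriate         30           12            18
         cannot_assess          5            2             3
...
Assessable claims: 45 of 50
Appropriate share of assessable: both 33% (public 48%, private 18%)
```

Of the 50 fixture claims, 45 carry enough documentation to judge the
package selection; only a third of those were selected appropriately, and
the public hospital's share (48%) is more than twice the private one's
(18%). The single biggest problem — 21 claims, 70% of the inappropriate
group — is palliative-package selection for chemotherapy started within
six months of breast surgery with no documented metastasis, the signature
of adjuvant therapy billed as palliative. Inspect any single verdict with
its evidence trail:

```r
audit_claim(fixture[3, ], load_catalog())
#> <claim_audit> CLM-PUB-03
#>   package:   inappropriate
#>   treatment: cannot_assess
#>   reason:    IN_NO_MET_WITHIN_6MO
#>   ...
```

Documentation cataloguing and claims-history metrics:

```r
tabulate_documents(fixture)   # per-document counts/percent by sector
g <- generate_cohort(generator_config(seed = 7))
history_metrics(g$history,
                setNames(g$cohort$hospital_id, g$cohort$patient_id),
                setNames(g$cohort$sector, g$cohort$patient_id))
```

A thin command-line front-end wraps the same functions:

```sh
Rscript inst/scripts/palliaudit.R generate --out out/gen --seed 7
Rscript inst/scripts/palliaudit.R audit --claims out/gen/cohort.csv \
    --history out/gen/history.csv --out out/audit
```

## Layout

- `R/` — cohort schema and I/O, drug catalog, audit engine, tabulation,
  synthetic generator, pipeline commands
- `inst/extdata/default_catalog.yaml` — default (illustrative) drug-role
  catalog; replace for real audits
- `vignettes/audit-methodology.Rmd` — the model, its assumptions, and the
  design decisions
- `tests/testthat/` — unit, property, and cohort-level suites, including a
  full decision-table oracle over the engine's discrete input space
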