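---
title: "Auditing palliative chemotherapy claims: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing palliative chemotherapy claims: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palliaudit)
```

## The audit problem

Indian public health insurance schemes reimburse hospitals through
predefined benefits packages. The catch-all "palliative chemotherapy —
unlisted regimen" package is meant for chemotherapy given to patients with
metastatic (incurable) cancer, but because it accepts any regimen it has
historically received little oversight. A clinical audit of such claims
asks, for each sampled claim: given the documentation the hospital filed,
was this package the right one to select, and was the care itself
guideline-concordant?

`palliaudit` encodes that audit as a deterministic rule engine. Its unit of
analysis is the *claim record*: identifiers, 15 document-presence flags,
and a clinical abstract (biopsy diagnosis, documented-metastasis status,
surgery type/date, chemotherapy claim date, administered drugs, the regimen
strings on the consent form and in the clinical notes, and whether prior
first-line therapy is documented). Absence of evidence is always explicit —
`metastasis_documented` is `"yes"` or `"no_documentation"`, never missing —
because the audit branches on lack of documentation, not on documented
absence.

## The decision sequence

`audit_claim()` applies fixed-order, first-match rules; every evaluated
rule is recorded in an evidence trail:

1. **Tissue diagnosis.** No biopsy or FNAC report → package selection
   cannot be assessed (`CA_NO_BIOPSY`).
2. **Internal consistency.** Consent-form and clinical-notes regimens both
   present but different after normalization → `CA_REGIMEN_DISCREPANCY`.
3. **Diagnosis.** Biopsy shows a variant breast condition or a non-breast
   cancer → `IN_NON_BREAST_DX`.
4. /5. **Palliative context.** Established when metastasis is documented
   *or* the surgery-to-chemotherapy gap exceeds six calendar months.
   Neither metastasis documentation nor a surgery date → `CA_NO_MET_NO_GAP`;
   no metastasis documentation with chemotherapy within six months of
   surgery → `IN_NO_MET_WITHIN_6MO` (the adjuvant-setting signature).
6. **Drug class.** Only non-chemotherapy agents (hormonal/targeted
   therapy) → `IN_NON_CHEMO_DRUGS`: the package pays for chemotherapy,
   so the selection is wrong even where the therapy may be sound.
7. /8. **Guideline role.** A first-line palliative role →
   `AP_FIRST_LINE`. Otherwise a second-line role →
   `AP_SECOND_LINE_WITH_FIRST_DOC` or `AP_SECOND_LINE_NO_FIRST_DOC`
   depending on documentation of prior first-line therapy.
9. **Fallthrough.** Chemotherapy holding no palliative role despite an
   established palliative context → `IN_NO_PALLIATIVE_ROLE`, with
   treatment inappropriate.

Document-sufficiency checks run before clinical checks so that every claim
receives exactly one reproducible reason even when several criteria apply;
the source determinations likewise assign a single reason per claim. The
reason prefix pins the package determination (`CA_*` → cannot assess,
`IN_*` → inappropriate, `AP_*` → appropriate), which gives the partition
identity the summaries rely on.

**Treatment determination.** Appropriate for `AP_FIRST_LINE` and
`AP_SECOND_LINE_WITH_FIRST_DOC`; inappropriate when the fallthrough fires
or when the per-claim expert-review override flag is set on an
inappropriate-package claim; cannot-assess otherwise. The published audit
reached its inappropriate-treatment verdicts by expert review and states no
mechanical criterion; the override flag is our reproducible stand-in for
that judgment, and it is deliberately restricted to claims whose package
determination is already definitive — claims the rules classify as
unassessable stay unassessable on both dimensions.

**Why a tenth reason code.** Three inappropriate-package claims in the
source audit also carried inappropriate treatment, and the published
reason rows cover only the other 27. With nine codes, the
reasons-partition-the-determination invariant is unsatisfiable; we
therefore give the fallthrough its own code, `IN_NO_PALLIATIVE_ROLE`,
rather than silently inflating one of the printed reason rows.

**A note on `unknown` biopsy diagnoses.** A present-but-illegible report
(`biopsy_diagnosis = "unknown"`) does not contradict breast cancer, so the
claim proceeds down the breast-cancer path rather than being forced into a
cannot-assess verdict; only the *absence* of the report blocks assessment.

## The six-month rule

The gap rule needs a precise boundary. We take "more than six months" to
mean the chemotherapy claim date is *strictly later* than the surgery date
advanced six calendar months, with end-of-month clamping
(`2019-08-31 + 6 months = 2020-02-29`); the anniversary day itself counts
as "within six months", resolving the boundary conservatively toward
inappropriate selection. `add_months_clamped()` implements the arithmetic
directly because base R's date sequences let short months overflow
(2019-08-31 + 6 months would land on 2020-03-02). The test suite checks the
clamped anniversary against an independent overflow-and-walk-back oracle
for every day in a two-year window, plus several thousand random
surgery/chemotherapy pairs.

## The drug catalog

Clinical guidelines define which agents count as first-line, second-line,
non-chemotherapy, or adjuvant; the engine only ever consumes these *roles*.
They live in a YAML catalog (`load_catalog()`) mapping normalized drug or
combination names (case- and whitespace-insensitive; combinations keyed as
`"a+b"` and matched against the joined, and sorted-joined, drug list) to
role sets. Roles are not mutually exclusive. The shipped default catalog is
a package-authored illustrative list — its `source` field says so — because
the authoritative guideline drug list is a configuration artifact, not code:
replacing the file changes no rule. Whole-regimen entries matter because a
named combination (such as doxorubicin + cyclophosphamide, "AC") can carry
an adjuvant role its components alone would not establish.

## Synthetic cohorts

Real claims for this package are confidential, so the package generates its
own test data at two levels.

`build_table2_fixture()` is deterministic: 50 claims (25 per sector) whose
clinical attribute patterns occur exactly as often, and with the same
sector split, as in the published determinations, and whose document flags
reproduce every cell of the published availability table. Crucially the
fixture stores *inputs only* — gap categories are realized as concrete
dates (60 days after surgery for the within-six-months pattern, 300 days
for the beyond pattern; arbitrary but fixed, since only the category
matters), drug names are drawn from the catalog by role, and the audit
engine produces the determinations. Where the published table prints no
sector split (the three override claims), the split is forced by
arithmetic: the printed public-column counts already sum to 25, so those
three claims are private. The appropriate-package rows mix both context
routes (documented metastasis and a more-than-six-month gap) so each is
exercised.

`generate_cohort()` is the seeded stochastic generalization: a
`generator_config()` sets the cohort size, a reason-pattern mix
(probabilities, or exact counts when they sum to the cohort size),
per-sector document-availability rates, and claims-history parameters. Its
defaults are the audited cohort's own frequencies: 25 patients per sector,
the pattern mix at the published counts over 50, document rates at the
published per-sector rates, histories with a mean of 14.7 claims per
patient, pooled same-hospital shares of 0.80 (public) and 0.96 (private),
and at most three distinct hospitals per patient. Document flags are drawn
independently at those rates except where a pattern constrains them (a
claim that must be assessable keeps a tissue-diagnosis report; a
discrepancy claim keeps its consent form). The generator's central
correctness property — auditing any generated claim returns exactly its
assigned pattern, at any seed — is what the property suite asserts.

What the generator does *not* emulate: correlation between document flags
within a claim, secular trends in claim dates, claim amounts and
reimbursement finance, hospital-level clustering beyond the two index
hospitals, and any association between documentation completeness and
appropriateness. Passing tests therefore demonstrate that the engine
implements the stated rules faithfully, not that the rules would perform
identically on real claims.

## Tabulation conventions

`tabulate_documents()` reports counts and percentages overall and per
sector, with the derived any-radiodiagnosis row (chest x-ray, CT and/or
ultrasound) computed as a union, never stored. Percentages are kept at full
precision internally and rendered to whole percent for display, matching
the reporting style of the source tables; rows sort by descending overall
percentage with ties broken by document code. `summarize_audit()` reports
the appropriate share on both the full-cohort and the assessable
denominators, because the two are easily conflated (15 of 45 assessable is
33%; the same 15 of 50 is 30%). The same-hospital claim share is pooled
over claims rather than averaged over patients — matching the phrasing of
the source — with the per-patient distribution also reported.

## Problem sizes and numerical choices

The test suite enumerates the engine's full discrete input space (3,456
combinations of biopsy availability, discrepancy state, diagnosis,
metastasis, gap category, regimen-role profile, prior-first-line flag, and
override) against an independently written decision-table oracle; runs the
generator–engine round trip at three seeds of 1,000 claims; and checks
stochastic recovery of the default mix at 5,000 claims within three
binomial standard errors. These sizes make every property run comfortably
on a single CPU in seconds while keeping the binomial bounds tight enough
to catch off-by-one-rule errors.

Degenerate inputs are defined, not errors: an empty cohort tabulates to
zeros and audits to an empty result; an empty catalog classifies everything
as unclassified (such claims fall through to `IN_NO_PALLIATIVE_ROLE` when
the context is established); an empty drug list behaves like an
unclassified regimen. A surgery date after the chemotherapy date is a
validation error, never silently reordered.

## Limitations

The engine reads the *documented* record only: it does not infer metastasis
from radiology report content, model doses, cycles, or biomarkers
(ER/PR/HER2), and it cannot recover information hospitals never filed. The
five-patient deep-record review of the source audit was qualitative and is
out of scope. The default drug catalog is illustrative; real audits must
supply the guideline-issued list. And the expert-override flag is an
honest interface to clinical judgment, not a replacement for it.
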