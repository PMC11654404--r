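# Default drug-role catalog shipped with palliaudit.
#
# Provenance: this list is a package-authored, synthetic illustrative
# stand-in assembled from standard breast-oncology usage. It is NOT a
# guideline-issued drug list; replace it with your scheme's authoritative
# catalog for real audits. The audit engine depends only on the roles, never
# on the drug names, so swapping the list does not change the rules.
#
# Roles: first_line_palliative, second_line_palliative, non_chemotherapy,
# adjuvant_regimen. An entry may carry several roles. Combination regimens
# are keyed by the joined drug names ("a+b"); lookups are case- and
# whitespace-insensitive.
source: >-
  palliaudit package default (synthetic illustrative stand-in for a
  guideline-issued first/second-line drug list; replace for real audits)
drugs:
  paclitaxel: [first_line_palliative]
  docetaxel: [first_line_palliative]
  nab-paclitaxel: [first_line_palliative]
  capecitabine: [second_line_palliative]
  gemcitabine: [second_line_palliative]
  vinorelbine: [second_line_palliative]
  eribulin: [second_line_palliative]
  tamoxifen: [non_chemotherapy]
  letrozole: [non_chemotherapy]
  anastrozole: [non_chemotherapy]
  exemestane: [non_chemotherapy]
  trastuzumab: [non_chemotherapy]
  palbociclib: [non_chemotherapy]
  zoledronic acid: [non_chemotherapy]
  doxorubicin: [adjuvant_regimen]
  adriamycin: [adjuvant_regimen]
  epirubicin: [adjuvant_regimen]
  cyclophosphamide: [adjuvant_regimen]
  5-fluorouracil: [adjuvant_regimen]
  methotrexate: [adjuvant_regimen]
  adriamycin+cyclophosphamide: [adjuvant_regimen]
  doxorubicin+cyclophosphamide: [adjuvant_regimen]
  5-fluorouracil+epirubicin+cyclophosphamide: [adjuvant_regimen]
  cyclophosphamide+methotrexate+5-fluorouracil: [adjuvant_regimen]
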