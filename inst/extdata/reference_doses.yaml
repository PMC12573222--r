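# Health-based reference doses for urinary-biomarker risk characterisation.
# Units are per kg body weight per day; values are converted to
# ug/kg-bw/day when loaded.
reference_doses:
  - analyte_id: MP
    value: 10
    units: mg
    dose_type: ADI
    source: "EFSA group ADI for methyl paraben and its sodium salt (0-10 mg/kg-bw/day)"
  - analyte_id: EP
    value: 10
    units: mg
    dose_type: ADI
    source: "EFSA group ADI for ethyl paraben and its sodium salt (0-10 mg/kg-bw/day)"
  - analyte_id: PP
    value: 1.25
    units: mg
    dose_type: ADI
    source: "EMA ADI for propyl paraben"
  - analyte_id: BPA
    value: 0.2
    units: ng
    dose_type: TDI
    source: "EFSA 2023 tolerable daily intake for bisphenol A"
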