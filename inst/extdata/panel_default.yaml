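# Default FI-lab reference panel: 35 commonly measured laboratory analytes
# with textbook adult reference intervals. Limits are inclusive (a value equal
# to a limit is normal). Sex-specific intervals where standard practice uses
# them. This file is configuration, not code: sites should substitute their
# own laboratory's intervals.
name: default-35
panel:
  - analyte_id: wbc
    units: 10^9/L
    lower: 3.5
    upper: 9.5
  - analyte_id: rbc
    units: 10^12/L
    male: {lower: 4.3, upper: 5.7}
    female: {lower: 3.8, upper: 5.1}
  - analyte_id: hemoglobin
    units: g/dL
    male: {lower: 13.5, upper: 17.5}
    female: {lower: 12.0, upper: 16.0}
  - analyte_id: hematocrit
    units: "%"
    male: {lower: 40, upper: 52}
    female: {lower: 36, upper: 48}
  - analyte_id: mcv
    units: fL
    lower: 80
    upper: 100
  - analyte_id: platelets
    units: 10^9/L
    lower: 150
    upper: 400
  - analyte_id: sodium
    units: mmol/L
    lower: 135
    upper: 145
  - analyte_id: potassium
    units: mmol/L
    lower: 3.5
    upper: 5.0
  - analyte_id: chloride
    units: mmol/L
    lower: 98
    upper: 108
  - analyte_id: calcium
    units: mg/dL
    lower: 8.5
    upper: 10.5
  - analyte_id: phosphate
    units: mg/dL
    lower: 2.5
    upper: 4.5
  - analyte_id: magnesium
    units: mg/dL
    lower: 1.7
    upper: 2.5
  - analyte_id: urea_nitrogen
    units: mg/dL
    lower: 8
    upper: 20
  - analyte_id: creatinine
    units: mg/dL
    male: {lower: 0.6, upper: 1.2}
    female: {lower: 0.5, upper: 1.0}
  - analyte_id: uric_acid
    units: mg/dL
    male: {lower: 3.5, upper: 7.2}
    female: {lower: 2.5, upper: 6.0}
  - analyte_id: glucose
    units: mg/dL
    lower: 70
    upper: 110
  - analyte_id: hba1c
    units: "%"
    lower: 4.6
    upper: 6.2
  - analyte_id: total_protein
    units: g/dL
    lower: 6.3
    upper: 8.0
  - analyte_id: albumin
    units: g/dL
    lower: 3.5
    upper: 5.0
  - analyte_id: total_bilirubin
    units: mg/dL
    lower: 0.2
    upper: 1.2
  - analyte_id: ast
    units: U/L
    lower: 10
    upper: 40
  - analyte_id: alt
    units: U/L
    lower: 7
    upper: 45
  - analyte_id: alp
    units: U/L
    lower: 40
    upper: 130
  - analyte_id: ggt
    units: U/L
    male: {lower: 10, upper: 70}
    female: {lower: 7, upper: 40}
  - analyte_id: ldh
    units: U/L
    lower: 120
    upper: 250
  - analyte_id: ck
    units: U/L
    male: {lower: 50, upper: 250}
    female: {lower: 40, upper: 200}
  - analyte_id: amylase
    units: U/L
    lower: 40
    upper: 130
  - analyte_id: total_cholesterol
    units: mg/dL
    lower: 130
    upper: 220
  - analyte_id: triglycerides
    units: mg/dL
    lower: 30
    upper: 150
  - analyte_id: hdl_cholesterol
    units: mg/dL
    lower: 40
    upper: 90
  - analyte_id: ldl_cholesterol
    units: mg/dL
    lower: 60
    upper: 140
  - analyte_id: crp
    units: mg/dL
    lower: 0
    upper: 0.3
  - analyte_id: iron
    units: ug/dL
    lower: 50
    upper: 170
  - analyte_id: tsh
    units: mIU/L
    lower: 0.4
    upper: 4.0
  - analyte_id: inr
    units: ratio
    lower: 0.9
    upper: 1.1
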