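# Default 40-item clinical (non-laboratory) frailty index schema, organised by
# the standard deficit-accumulation domains: symptoms and signs, body mass
# index, comorbidities, functional ability, cognitive status, and sensory
# function. Item values are 0 (deficit absent), 0.5 (partial), or 1 (present).
# Item identities are a generic schema intended to be replaced by each site's
# own deficit list; only the count (40) and the value domain are load-bearing.
name: default-40
items:
  - {item_id: fic01, domain: symptoms, label: fatigue}
  - {item_id: fic02, domain: symptoms, label: appetite_loss}
  - {item_id: fic03, domain: symptoms, label: weight_loss}
  - {item_id: fic04, domain: symptoms, label: dyspnea}
  - {item_id: fic05, domain: symptoms, label: chest_pain}
  - {item_id: fic06, domain: symptoms, label: edema}
  - {item_id: fic07, domain: symptoms, label: dizziness}
  - {item_id: fic08, domain: symptoms, label: sleep_disturbance}
  - {item_id: fic09, domain: symptoms, label: urinary_incontinence}
  - {item_id: fic10, domain: symptoms, label: constipation}
  - {item_id: fic11, domain: bmi, label: abnormal_bmi}
  - {item_id: fic12, domain: comorbidity, label: hypertension}
  - {item_id: fic13, domain: comorbidity, label: diabetes}
  - {item_id: fic14, domain: comorbidity, label: heart_disease}
  - {item_id: fic15, domain: comorbidity, label: stroke_history}
  - {item_id: fic16, domain: comorbidity, label: respiratory_disease}
  - {item_id: fic17, domain: comorbidity, label: kidney_disease}
  - {item_id: fic18, domain: comorbidity, label: liver_disease}
  - {item_id: fic19, domain: comorbidity, label: cancer_history}
  - {item_id: fic20, domain: comorbidity, label: osteoporosis_fracture}
  - {item_id: fic21, domain: comorbidity, label: parkinsonism}
  - {item_id: fic22, domain: function, label: adl_feeding}
  - {item_id: fic23, domain: function, label: adl_transfer}
  - {item_id: fic24, domain: function, label: adl_grooming}
  - {item_id: fic25, domain: function, label: adl_toilet_use}
  - {item_id: fic26, domain: function, label: adl_bathing}
  - {item_id: fic27, domain: function, label: adl_walking}
  - {item_id: fic28, domain: function, label: adl_stairs}
  - {item_id: fic29, domain: function, label: adl_dressing}
  - {item_id: fic30, domain: function, label: adl_bowel_control}
  - {item_id: fic31, domain: function, label: adl_bladder_control}
  - {item_id: fic32, domain: function, label: device_dependence}
  - {item_id: fic33, domain: function, label: bed_rest}
  - {item_id: fic34, domain: cognition, label: memory_impairment}
  - {item_id: fic35, domain: cognition, label: disorientation}
  - {item_id: fic36, domain: cognition, label: impaired_judgement}
  - {item_id: fic37, domain: cognition, label: delirium_risk}
  - {item_id: fic38, domain: sensory, label: vision_deficit}
  - {item_id: fic39, domain: sensory, label: hearing_deficit}
  - {item_id: fic40, domain: sensory, label: speech_communication}
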