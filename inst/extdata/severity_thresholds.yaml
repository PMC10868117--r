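# Default severity cutoffs for the lab-based labels, in the canonical unit
# of each analyte. These defaults are drawn from widely used guideline
# families and are editable stand-ins: any deployment should review them
# against local practice.
#
# direction 'below': a positive label requires the admission extremum to be
# strictly below the cutoff; 'above': strictly above. Severity is nested
# (severe implies moderate implies mild), which the cutoff ordering
# guarantees. AKI (hypercreatinemia) uses multipliers of the age-group
# upper reference bound (threshold_mode: relative_to_reference_high).
aki:
  analyte: creatinine
  direction: above
  threshold_mode: relative_to_reference_high
  unit: umol/L
  mild: 1.5
  moderate: 2.0
  severe: 3.0
hyperkalemia:
  analyte: potassium
  direction: above
  threshold_mode: absolute
  unit: mmol/L
  mild: 5.5
  moderate: 6.0
  severe: 6.5
hypoglycemia:
  analyte: glucose
  direction: below
  threshold_mode: absolute
  unit: mmol/L
  mild: 3.9
  moderate: 3.0
  severe: 2.2
hyponatremia:
  analyte: sodium
  direction: below
  threshold_mode: absolute
  unit: mmol/L
  mild: 135
  moderate: 130
  severe: 125
anemia:
  analyte: hemoglobin
  direction: below
  threshold_mode: absolute
  unit: g/L
  mild: 110
  moderate: 90
  severe: 70
neutropenia:
  analyte: anc
  direction: below
  threshold_mode: absolute
  unit: 10^9/L
  mild: 1.5
  moderate: 1.0
  severe: 0.5
thrombocytopenia:
  analyte: platelets
  direction: below
  threshold_mode: absolute
  unit: 10^9/L
  mild: 150
  moderate: 100
  severe: 50
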