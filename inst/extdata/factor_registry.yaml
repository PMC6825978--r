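# Default deficit factor registry: the 23 factors and their adverse cutoffs.
# Edit a copy of this file and pass it to read_factor_registry() to run
# cutoff sensitivity analyses.
- {factor: readmission,       source: readmitted_30d,            rule: is_true,                                units: yes/no}
- {factor: marital_support,   source: marital_status,            rule: in_set,  levels: [single, divorced, widowed], units: category}
- {factor: language,          source: language,                  rule: in_set,  levels: [not_english],         units: category}
- {factor: fall_risk,         source: fall_risk,                 rule: in_set,  levels: [high],                units: category}
- {factor: healthcare_visits, source: healthcare_visits_6mo,     rule: gt,      threshold: 2,                  units: visits}
- {factor: bmi,               source: bmi,                       rule: lt,      threshold: 19,                 units: kg/m^2}
- {factor: corrected_calcium, source: corrected_calcium,         rule: ge,      threshold: 11,                 units: mg/dL}
- {factor: creatinine,        source: creatinine,                rule: gt,      threshold: 1.3,                units: mg/dL}
- {factor: ecog,              source: ecog_ps,                   rule: in_set,  levels: [2, 3, 4],             units: grade}
- {factor: nlr,               source: nlr,                       rule: gt,      threshold: 5,                  units: index}
- {factor: neutrophils,       source: neutrophils,               rule: lt,      threshold: 1.8,                units: k/uL}
- {factor: plr,               source: plr,                       rule: gt,      threshold: 250,                units: index}
- {factor: platelets,         source: platelets,                 rule: outside, threshold: 150, threshold2: 450, units: k/uL}
- {factor: hemoglobin,        source: hemoglobin,                rule: lt,      threshold: 12,                 units: g/dL}
- {factor: length_of_stay,    source: length_of_index_admission, rule: gt,      threshold: 5,                  units: days}
- {factor: lymphocytes,       source: lymphocytes,               rule: lt,      threshold: 1.1,                units: k/uL}
- {factor: sii,               source: sii,                       rule: gt,      threshold: 1600,               units: index}
- {factor: albumin,           source: albumin,                   rule: lt,      threshold: 3.5,                units: g/dL}
- {factor: sodium,            source: sodium,                    rule: lt,      threshold: 135,                units: mmol/L}
- {factor: wbc,               source: wbc,                       rule: gt,      threshold: 11,                 units: k/uL}
- {factor: medications,       source: n_medications,             rule: gt,      threshold: 5,                  units: count}
- {factor: pni,               source: pni,                       rule: lt,      threshold: 45,                 units: index}
- {factor: metastasis,        source: metastasis,                rule: is_true,                                units: yes/no}
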