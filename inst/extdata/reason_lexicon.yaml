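# Default chief-complaint grouping lexicon: category -> keywords.
# Matching is case-insensitive substring search, categories in file order,
# first match wins; unmatched complaints map to "other".
pain: [pain]
neurologic: [syncope, dizziness, headache, diplopia, ataxia, neurolog, seizure]
dyspnea: [shortness of breath, dyspnea, hypoxia, breath]
chemo_side_effect: [nausea, vomiting, diarrhea, chemotherapy]
abnormal_findings: [abnormal, ekg, electrocardiogram, lab value, laboratory, imaging, radiograph]
dehydration: [dehydrat]
fever: [fever, febrile, neutropenic fever]
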