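# Illustrative keyword rules: phrase <TAB> comma-separated codes <TAB> section
# MH rows: chronic diseases often absent from discharge diagnoses.
# SE rows: procedure mentions that carry ICD-10-PCS codes.
hypertension	I10	MH
chronic kidney disease	N18.9	MH
chronic kidney insufficiency	N18.9	MH
diabetes mellitus	E11.9	MH
heart failure	I50.9	MH
atrial fibrillation	I48.91	MH
asthma	J45.909	MH
chronic obstructive pulmonary disease	J44.9	MH
hyperlipidemia	E78.5	MH
coronary artery disease	I25.10	MH
old stroke	I69.30	MH
gout	M10.9	MH
hypothyroidism	E03.9	MH
hepatitis b carrier	B18.1	MH
chronic hepatitis c	B18.2	MH
liver cirrhosis	K74.60	MH
anemia	D64.9	MH
dementia	F03.90	MH
parkinson disease	G20	MH
epilepsy	G40.909	MH
peptic ulcer disease	K27.9	MH
endoscope	0DJ08ZZ	SE
esophagogastroduodenoscopy	0DJ08ZZ	SE
biopsy	0DB68ZX	SE
colonoscopy	0DJD8ZZ	SE
bronchoscopy	0BJ08ZZ	SE
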