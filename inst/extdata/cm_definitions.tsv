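# code <TAB> official definition text
N39.0	Urinary tract infection, site not specified.
I10	Essential (primary) hypertension
I11.0	Hypertensive heart disease with heart failure
I12.9	Hypertensive chronic kidney disease with stage 1 through stage 4 chronic kidney disease
I13.0	Hypertensive heart and chronic kidney disease with heart failure
E10.9	Type 1 diabetes mellitus without complications
E11.9	Type 2 diabetes mellitus without complications
J18.9	Pneumonia, unspecified organism
I50.9	Heart failure, unspecified
N18.1	Chronic kidney disease, stage 1
N18.4	Chronic kidney disease, stage 4 (severe)
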