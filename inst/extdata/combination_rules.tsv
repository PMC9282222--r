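# trigger <TAB> companion groups (";" between checks, "|" between alternatives) <TAB> combo code <TAB> replacement (combination-code definition)
# Most specific rule first: once it fires, the trigger mention is gone.
hypertension	chronic kidney disease|chronic kidney insufficiency;heart failure	I13.0	hypertensive heart and chronic kidney disease with heart failure
hypertension	heart failure	I11.0	hypertensive heart disease with heart failure
hypertension	chronic kidney disease|chronic kidney insufficiency	I12.9	hypertensive chronic kidney disease
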