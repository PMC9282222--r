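# name <TAB> matcher ({n} = integer slot) <TAB> template ({w} = number word)
type	type {n}	type {w}
stage	stage {n}	stage {w}
grade	grade {n}	grade {w}
weeks-gestation	{n} weeks gestation	{w} weeks gestation
scale	scale {n}	scale {w}
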