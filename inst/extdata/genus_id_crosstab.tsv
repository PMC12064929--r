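genetic	morph	count
Entosphenus	Entosphenus	634
Entosphenus	Lampetra	11
Lampetra	Entosphenus	0
Lampetra	Lampetra	525
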