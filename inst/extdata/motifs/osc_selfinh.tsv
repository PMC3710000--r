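# fully compressed negative feedback loop
A	-	A
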