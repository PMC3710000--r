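# coupled positive feedback: mutual inhibition plus autocatalysis
A	-	B
B	-	A
A	+	A
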