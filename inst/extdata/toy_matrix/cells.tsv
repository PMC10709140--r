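cell_id	x	y	z	sample_id	batch_id
c1	0.5	1.0	0	S1	B1
c2	2.5	1.5	0	S1	B1
c3	4.0	2.0	0	S1	B1
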