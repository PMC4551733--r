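build	complex	it	del	ins	ec	mc	total
UMD3.1	1374	55	1207	461	1320	337	4754
Btau4.6	2331	102	2596	782	1166	486	7463
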