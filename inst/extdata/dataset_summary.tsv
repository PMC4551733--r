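n_rmaps	total_mass_mb	min_kb	max_kb	genome_size_mb
1908396	758574.97	300	2515.20	2800
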