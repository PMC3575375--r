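# Four-haplotype, four-site binary sample (rows = distinct haplotypes,
# columns = segregating sites, 0 = ancestral, 1 = derived).
M1	M2	M3	M4	freq
0	1	1	0	1
1	1	1	0	1
0	0	0	0	1
0	0	0	1	1
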