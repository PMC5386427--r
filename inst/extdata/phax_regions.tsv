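phax	chrom	start	end	called_bp
3115	chrX	39519963	39524945	4983
5574	chrX	94544032	94582132	36857
8913	chrX	141656627	141662612	5763
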