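chrom	start	end	strand	feature
synthetic_wp_scaffold	1	60	+	five_prime_UTR
synthetic_wp_scaffold	61	160	+	CDS
synthetic_wp_scaffold	211	350	+	CDS
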