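#name	start	end	strand	sequence	role
gRNA1	88	108	+	CGGTATCCAATGCACAAAGTT	guide
gRNA2	787	767	-	TAATCCTGAGAAAAGATAAAG	guide
gRNA3	826	806	-	AATAGTGAGCGCAGCGGTGCT	guide
fragA	52	155	.	.	fragment
fragB	730	840	.	.	fragment
fragC	1580	1681	.	.	fragment
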