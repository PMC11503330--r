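# Worked-example validation panel: spondyloarthropathy vs all-other-subjects contrast.
peptide_id	sequence	p_cor	p_fold	p_pval	e_cor	e_fold	e_p
Q13330-195	ETQVWEAHNPLTDKQI	0.756	0.828	0.844	0.17	4.1	0.721
Q9NUL5-255	LSQGGLLEDLDNLILE	0.618	0.928	0.876	0.40	1.4	0.123
Q9Y3Y4-315	DACTTEKSNKSSLHPN	0.898	0.786	0.674	0.26	1.8	0.089
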