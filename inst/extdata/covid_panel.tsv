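# Worked-example validation panel: COVID-19-convalescent vs naive contrast.
# p_*: predicted probabilities of meeting each ELISA criterion; e_*: empiric ELISA summaries.
peptide_id	sequence	p_cor	p_fold	p_pval	e_cor	e_fold	e_p
surf-1253	CCKFDEDDSEPVLKGV	0.63	0.60	0.98	0.83	8.75	2.3e-09
surf-814	KRSFIEDLLFNKVTLA	0.55	0.44	0.98	0.59	1.98	6.0e-05
mem-8	ITVEELKKLLEQWNLV	0.53	0.60	0.97	0.83	51.52	1.1e-08
nucl-390	QTVTLLPAADLDDFSK	0.64	0.51	0.98	0.82	92.32	1.7e-09
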