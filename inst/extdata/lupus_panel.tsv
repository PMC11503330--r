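# Worked-example validation panel: lupus vs all-other-subjects contrast.
peptide_id	sequence	p_cor	p_fold	p_pval	e_cor	e_fold	e_p
Q9Y468-515	QPPLGPREPSSASPGG	0.89	0.89	0.84	0.44	9.3	0.013
Q9BWU1-35	VYKARRKDGKDEKEYA	0.80	0.88	0.83	0.52	1.6	0.003
Q96GP6-845	TPIQKPPRKKSREAAG	0.77	0.93	0.84	0.49	3.5	0.044
O75037-125	AERKRRAQEQGVAGPE	0.81	0.89	0.86	0.46	2.5	0.009
Q8TE54-327	AQGSAKKFKYSIDDNQ	0.95	0.88	0.80	0.36	2.2	0.025
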