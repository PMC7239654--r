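panel	sample	ec50_nM	se_nM
wt_hap1	RSPO3_WT	0.048	0.005
wt_hap1	RSPO3_dTSPBR_KRE	0.63	0.02
wt_hap1	RSPO3_dTSPBR	3.93	1.0
lgr_ko	RSPO3_WT	0.092	0.007
hs20_wt_hap1	RSPO3_dTSPBR	9.8	0.92
hs20_wt_hap1	RSPO3_dTSPBR_HS20	0.20	0.017
hs20_wt_hap1	RSPO3_dTSPBR_HS20_R67A_Q72A	2.0	0.26
hs20_wt_hap1	RSPO3_dTSPBR_HS20_F106E_F110E	0.68	0.014
hs20_lgr_ko	RSPO3_dTSPBR_HS20	1.1	0.12
hs20_lgr_ko	RSPO3_dTSPBR_HS20_F106E_F110E	0.49	0.07
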