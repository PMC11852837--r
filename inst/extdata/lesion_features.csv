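lesion_id,fa_median,cl_median,rcbv_max,pp_printed_pct,reference_label,reference_source
1,0.09,0.03,1.6,1,PsP,histology
2,0.15,0.05,7.94,99,TP,histology
3,0.08,0.03,2.02,1,PsP,histology
4,0.21,0.09,2.02,70,TP,histology
5,0.35,0.14,2.0,99,TP,modified_RANO
6,0.07,0.04,3.08,0.1,PsP,modified_RANO
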