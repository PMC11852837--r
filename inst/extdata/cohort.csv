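patient_id,gender,age_years,kps,surgery,mgmt_methylated,soc_completed,additional_treatment,os_years
1,F,50,90,Near total resection,TRUE,TRUE,Calcium channel antagonist,12.3
2,F,56,70-100,Near total resection,TRUE,TRUE,Antiangiogenic therapy,5.1
3,F,34,70-90,Near total resection,TRUE,TRUE,Immunotherapy,11.1
4,F,57,90-100,Near total resection,TRUE,TRUE,Immunotherapy,5.2
5,F,67,100,Complete resection,FALSE,TRUE,Tumor-Treating Fields,6.8
6,F,63,90-100,Near total resection,TRUE,TRUE,Immunotherapy,5.2
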