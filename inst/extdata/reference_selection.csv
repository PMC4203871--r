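step,variable,auc
1,low_cardiac_output,0.7442
2,postop_creatinine,0.8342
3,ecc_time,0.8507
4,age,0.8551
5,postop_bilirubin,0.8589
6,chronic_dialysis,0.8612
7,acute_mi,0.8631
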