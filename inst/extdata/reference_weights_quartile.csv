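feature,Q1,Q2,Q3,Q4
postop_creatinine,-0.8848,-0.7004,-0.0678,1.0344
ecc_time,-0.6738,-0.3335,-0.1140,0.7261
age,-0.5917,-0.1154,-0.0278,0.5111
postop_bilirubin,-0.7184,-0.4112,-0.0163,0.7972
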