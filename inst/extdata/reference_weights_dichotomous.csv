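feature,no,yes
low_cardiac_output,-0.7418,2.0920
chronic_dialysis,-0.0305,2.3647
acute_mi,-0.0692,1.5864
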