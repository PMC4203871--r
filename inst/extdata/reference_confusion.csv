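tn,fp,fn,tp
2403,492,93,268
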