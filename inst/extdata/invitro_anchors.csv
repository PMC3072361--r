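day,metric,mean,sd
3,cell_number,8.9,NA
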