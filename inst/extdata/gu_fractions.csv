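subset,group,mean_pct,sd_pct,n
high,young,1.7,1.5,3
high,old,5.4,3.5,7
inter,young,66.5,36.9,3
inter,old,66.4,22.5,7
low,young,31.8,36.7,3
low,old,28.2,21.7,7
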