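quantity,value
tpc_mean,4286
tpc_median,3787
tpc_min,1070
tpc_max,18103
anthocyanin_mean,61.3
anthocyanin_median,17.7
anthocyanin_min,0.3
anthocyanin_max,920
tpc_mean_purple_flesh,6383
tpc_mean_pink_flesh,3937
tpc_mean_cream_flesh,3999
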