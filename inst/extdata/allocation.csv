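geo_stratum,arc_stratum,n_cos_per_cea,n_drivers_per_cos
low_concentration,low,2,2
low_concentration,intermediate,2,2
low_concentration,high,2,2
high_concentration,low,2,2
high_concentration,intermediate,3,2
high_concentration,high,3,4
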