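phase,t_start,t_end,prop_exp,prop_fov,prop_time,repeatability_sd,r,c
lag,0,2,0.3207,0.6707,0.0086,0.4867,0.8313,10.9
early,2,4,0.5831,0.4033,0.0137,0.3186,0.8751,15.0
late,4,8,0.4540,0.5151,0.0309,0.2148,0.9129,22.0
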