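outcome,mode,group,n_subjects,events,person_days,incidence_density,cumulative_incidence_pct,ci_low,ci_high
stroke,ITT,warfarin,4,1,2025,49.38,25,0.63,139.29
stroke,ITT,noac,4,2,1660,120.48,50,6.06,180.62
stroke,AT,warfarin,4,1,745,134.23,25,0.63,139.29
stroke,AT,noac,4,1,1590,62.89,25,0.63,139.29
ich,ITT,warfarin,5,1,2855,35.03,20,0.51,111.43
ich,ITT,noac,5,1,3070,32.57,20,0.51,111.43
ich,AT,warfarin,5,1,1575,63.49,20,0.51,111.43
ich,AT,noac,5,1,2370,42.19,20,0.51,111.43
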