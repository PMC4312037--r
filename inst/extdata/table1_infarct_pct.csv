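subject_id,ct_infarct_pct,hist_infarct_pct,motion_artifact
1,24.8,20.2,FALSE
2,32.7,33.2,FALSE
3,13.3,20.6,FALSE
4,35.7,36.5,FALSE
5,37.6,26.2,TRUE
6,34.0,33.8,FALSE
7,27.0,30.9,FALSE
8,52.7,42.5,FALSE
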