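subject_id,walking_speed_pre,walking_speed_post,cadence_pre,cadence_post,step_length_pre,step_length_post,running_speed_pre,running_speed_post
1,0.92,1.25,104,122,0.5,0.6,1.06,1.36
2,1.44,1.67,117,126,0.7,0.8,2.08,2.69
3,1.5,1.5,114,116,0.8,0.8,2.42,3.03
4,1,1.44,100,124,0.6,0.7,1.58,1.75
5,1.22,1.39,116,120,0.6,0.7,1.25,2.11
6,1.25,1.39,111,116,0.7,0.7,1.58,1.86
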