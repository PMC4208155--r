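subject_id,time_per_step_up_pre,time_per_step_up_post,time_per_step_down_pre,time_per_step_down_post,max_flexion_up_pre,max_flexion_up_post,max_flexion_down_pre,max_flexion_down_post,flexion_at_heelstrike_down_pre,flexion_at_heelstrike_down_post
1,0.6,0.58,0.54,0.51,78,84,81,84,25,27
2,0.5,0.43,0.51,0.41,74,77,72,69,22,26
3,0.51,0.5,0.49,0.4,83,78,70,69,6,20
4,0.75,0.64,0.59,0.58,49,87,36,74,8,12
5,0.57,0.5,0.53,0.44,93,75,101,78,18,24
6,0.66,0.67,0.65,0.53,86,72,84,84,7,25
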