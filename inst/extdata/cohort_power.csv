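subject_id,power_acceleration_pre,power_acceleration_post,power_deceleration_pre,power_deceleration_post
1,2,1.4,4.2,3.1
2,5.7,2.6,2.1,3.4
3,7.4,4.2,1.7,2.9
4,3.4,3.1,1.9,2.3
5,2.2,3.3,1.8,3.4
6,1.8,2.8,1.9,2.5
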