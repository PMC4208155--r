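subject_id,side,knee_system,age,sex,bmi,ucla,kss_pre,kss_post,oks_pre,oks_post
1,R,UKA,52,M,29.4,7,38,37,18,22
2,R,TKA,57,F,24.2,7,23,91,29,44
3,R,TKA,63,M,22.7,8,33,88,28,43
4,L,TKA,68,M,27.1,6,34,80,22,35
5,L,TKA,57,F,28.9,7,44,79,34,38
6,L,UKA,64,F,24.5,7,49,82,30,36
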