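subject_id,arat_pre,arat_post,delta_arat,delta_fmue,roll_pre,roll_post,pitch_pre,pitch_post,yaw_pre,yaw_post,total_time_pre_s,total_time_post_s
1,30,53,23,11,26.3,39.2,36.6,45.9,54.1,81.8,203,96.3
2,14,18,4,9,20.8,27.2,24.0,32.0,49.0,62.8,337,295
5,49,55,6,10,46.2,42.6,38.2,46.0,93.2,87.5,133,149
6,51,55,4,9,45.9,76.0,33.3,44.4,59.4,120,126,117
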