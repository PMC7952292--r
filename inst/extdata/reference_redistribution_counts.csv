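dimension,level_3L,level_5L,n
mobility,1,1,2857
mobility,1,2,136
mobility,2,2,304
mobility,2,3,270
mobility,2,4,233
mobility,3,4,9
mobility,3,5,15
self_care,1,1,3521
self_care,1,2,37
self_care,2,2,127
self_care,2,3,109
self_care,2,4,36
self_care,3,4,12
self_care,3,5,8
usual_activities,1,1,3066
usual_activities,1,2,99
usual_activities,2,2,262
usual_activities,2,3,178
usual_activities,2,4,63
usual_activities,3,4,29
usual_activities,3,5,14
pain_discomfort,1,1,1780
pain_discomfort,1,2,300
pain_discomfort,2,2,781
pain_discomfort,2,3,617
pain_discomfort,2,4,204
pain_discomfort,3,4,70
pain_discomfort,3,5,10
anxiety_depression,1,1,2172
anxiety_depression,1,2,391
anxiety_depression,2,2,685
anxiety_depression,2,3,349
anxiety_depression,2,4,93
anxiety_depression,3,4,26
anxiety_depression,3,5,11
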