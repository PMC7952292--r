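dimension,inconsistency_pct
mobility,3.3
self_care,2.5
usual_activities,5.8
pain_discomfort,4.8
anxiety_depression,5.7
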