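patient_id,age,sex,smoke,CFR,Rest_WMSI,N.vessels,death,follow_up_months
p001,71,male,yes,1.8,1.9,2,no,19
p002,66,female,no,2.0,1.0,0,no,19
p003,58,male,yes,2.6,1.0,0,no,19
p004,80,female,no,1.4,2.2,3,yes,7
p005,64,male,no,,1.0,1,no,19
p006,69,female,yes,2.1,1.6,0,no,19
p007,75,male,no,1.9,1.5,2,yes,12
p008,49,female,no,3.1,1.0,0,no,19
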