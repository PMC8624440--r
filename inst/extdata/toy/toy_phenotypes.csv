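subject_id,af_case,sex,age,bmi,pah,chf,chd,stroke,diabetes,dyslipidemia,chronic_resp,duration_months,age_at_onset,recurred,ef_percent,lavi
S00001,1,female,65,31.9,1,1,0,0,0,0,0,163.3,64.3,1,,
S00002,1,male,73.7,31.2,1,1,0,0,1,0,0,12.5,75.2,1,,
S00003,1,female,45.8,30.4,1,1,1,0,0,1,0,39.3,49,0,,
S00004,1,female,43.9,30.6,1,1,0,0,0,0,0,15.1,55.5,0,,
S00005,1,female,70.5,20.3,1,0,0,0,0,0,0,21.6,57.5,0,,
S00006,1,male,58.1,29.4,0,1,0,0,0,1,1,29.7,72.5,1,,
S00007,1,female,60.3,43,1,1,1,0,0,0,0,17.9,76.2,,,
S00008,1,female,62.7,27.4,1,1,1,0,0,1,0,37.9,64.9,,,
S00009,0,female,52.9,25.5,0,1,0,1,0,0,0,,,,,
S00010,0,female,61.4,31.3,1,0,0,0,0,0,0,,,,,
S00011,0,female,67.5,19.4,1,0,1,0,1,1,0,,,,,
S00012,0,female,63.2,26.8,0,0,0,0,0,0,0,,,,,
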