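participant_id,date,result,condom_use
P1,2017-07-10,negative,Never
P1,2017-09-30,negative,Ever
P1,2017-12-20,negative,Ever
P1,2018-03-25,negative,Consistent
P2,2017-08-01,negative,Consistent
P2,2017-12-15,negative,Ever
P2,2018-05-01,negative,Ever
P3,2017-09-01,positive,Uncertain
P4,2018-05-01,negative,Consistent
P5,2017-07-15,negative,Uncertain
P5,2017-10-10,negative,Never
P5,2018-01-05,positive,Uncertain
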