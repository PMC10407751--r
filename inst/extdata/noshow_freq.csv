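clinic_id,no_shows,frequency
1,1,10
1,2,6
1,3,7
1,4,13
1,5,3
1,6,17
1,7,14
1,8,10
1,9,5
1,10,3
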