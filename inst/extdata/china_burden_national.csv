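item,an_2000_2021,an_2022,af_2000_2021,af_2022
non_accidental,35987,62961,11.01,18.11
cardiovascular,23402,40567,15.32,24.33
respiratory,4745,7721,11.63,20.50
other,7395,13818,5.55,9.64
male,15089,26317,8.13,13.25
female,20512,35876,14.54,24.08
age_0_64,4196,5763,4.69,7.69
age_65p,29951,56208,13.15,21.64
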