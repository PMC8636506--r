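subject_id,roi_value,impaired
P01,0.15,FALSE
P02,0.153,FALSE
P03,0.156,FALSE
P04,0.158,FALSE
P05,0.16,FALSE
P06,0.162,FALSE
P07,0.164,FALSE
P08,0.166,FALSE
P09,0.168,FALSE
P10,0.17,FALSE
P11,0.171,FALSE
P12,0.172,FALSE
P13,0.19,FALSE
P14,0.195,FALSE
P15,0.151,TRUE
P16,0.154,TRUE
P17,0.1864,TRUE
P18,0.188,TRUE
P19,0.192,TRUE
P20,0.196,TRUE
P21,0.198,TRUE
P22,0.2,TRUE
P23,0.202,TRUE
P24,0.205,TRUE
P25,0.21,TRUE
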