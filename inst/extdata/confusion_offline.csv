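"category","Happy-M","Sad-M","Happy-F","Sad-F","error"
"Happy-M",16,0,0,0,"0.0%"
"Sad-M",2,13,0,0,"13.3%"
"Happy-F",0,0,17,1,"5.6%"
"Sad-F",0,0,0,12,"0.0%"
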