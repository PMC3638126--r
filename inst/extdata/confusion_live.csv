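"category","Happy-M","Sad-M","Happy-F","Sad-F","error"
"Happy-M",22,0,0,0,"0.0%"
"Sad-M",0,16,0,0,"0.0%"
"Happy-F",0,0,19,1,"5.0%"
"Sad-F",0,0,0,19,"0.0%"
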