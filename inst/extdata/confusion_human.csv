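"category","Anger","Fear","Happy","Sad","error"
"Anger",62,3,5,0,"11.4%"
"Fear",5,62,1,2,"11.4%"
"Happy",5,8,56,1,"20.0%"
"Sad",0,1,1,68,"2.9%"
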