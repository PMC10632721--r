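respondent_id,day,va_veg,dglv,other_veg,va_fruit,citrus,other_fruit
P01,1,1,1,1,0,0,1
P01,2,0,1,1,0,1,0
P02,1,1,0,1,0,0,0
P02,2,0,1,1,1,0,1
P03,1,0,1,0,0,0,1
P03,2,1,1,1,0,0,0
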