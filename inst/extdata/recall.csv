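respondent_id,day,item,grams
P01,1,carrot,40
P01,1,spinach,85.5
P01,1,tomato,60
P01,1,banana,110
P01,1,rice,250
P01,2,kale,70
P01,2,tomato,12
P01,2,orange,130
P01,2,rice,300
P02,1,carrot,8
P02,1,mushroom,55
P02,1,rice,220
P02,2,spinach,95
P02,2,tomato,45
P02,2,mango,140
P02,2,apple,90
P02,2,rice,180
P03,1,kale,60
P03,1,banana,95
P03,1,rice,260
P03,2,pumpkin,75
P03,2,spinach,80
P03,2,tomato,50
P03,2,rice,240
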