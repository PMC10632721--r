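item,group,sentinel
carrot,va_veg,1
pumpkin,va_veg,1
spinach,dglv,1
kale,dglv,0
tomato,other_veg,1
mushroom,other_veg,0
mango,va_fruit,1
papaya,va_fruit,0
orange,citrus,1
tangerine,citrus,0
banana,other_fruit,1
apple,other_fruit,0
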