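item,response_level,coefficient
(intercept),,0.50
item_1,1,0.00
item_1,2,0.01
item_1,3,0.02
item_1,4,0.03
item_1,5,0.04
item_2,1,0.00
item_2,2,0.01
item_2,3,0.02
item_2,4,0.03
item_2,5,0.04
item_3,1,0.00
item_3,2,0.01
item_3,3,0.02
item_3,4,0.03
item_3,5,0.04
item_4,1,0.00
item_4,2,0.01
item_4,3,0.02
item_4,4,0.03
item_4,5,0.04
item_5,1,0.00
item_5,2,0.01
item_5,3,0.02
item_5,4,0.03
item_5,5,0.04
item_6,1,0.00
item_6,2,0.01
item_6,3,0.02
item_6,4,0.03
item_6,5,0.04
item_7,1,0.00
item_7,2,0.01
item_7,3,0.02
item_7,4,0.03
item_7,5,0.04
item_8,1,0.00
item_8,2,0.01
item_8,3,0.02
item_8,4,0.03
item_8,5,0.04
item_9,1,0.00
item_9,2,0.01
item_9,3,0.02
item_9,4,0.03
item_9,5,0.04
item_10,1,0.00
item_10,2,0.01
item_10,3,0.02
item_10,4,0.03
item_10,5,0.04
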