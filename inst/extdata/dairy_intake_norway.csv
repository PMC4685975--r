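product,conc_ug_per_100g,men,women,toddlers,pregnant
milk,20,340,204,316,308
flavored_milk,16,21,13,4,43
yoghurt,19,23,32,71,67
cheese,35,40,36,12,16
whey_cheese,140,6,6,10,6
cream_products,19,22,21,8,17
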