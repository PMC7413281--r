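u	v	category	weight
手部	手	body_structure	1.0
足部	足	body_structure	1.0
头部	头	body_structure	1.0
肩部	肩	body_structure	1.0
腰部	腰	body_structure	1.0
颈部	颈	body_structure	1.0
背部	背	body_structure	1.0
膝部	膝	body_structure	1.0
肘部	肘	body_structure	1.0
腕部	腕	body_structure	1.0
手臂	前肢	body_structure	0.9
i型	i 型	type_stage	1.0
ii型	ii 型	type_stage	1.0
iii型	iii 型	type_stage	1.0
1型	i型	type_stage	1.0
2型	ii型	type_stage	1.0
儿童	小儿	age_group	0.9
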