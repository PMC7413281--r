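term	category
手部	body_structure
手	body_structure
足部	body_structure
足	body_structure
头部	body_structure
头	body_structure
肩部	body_structure
肩	body_structure
腰部	body_structure
腰	body_structure
颈部	body_structure
颈	body_structure
背部	body_structure
背	body_structure
膝部	body_structure
膝	body_structure
肘部	body_structure
肘	body_structure
腕部	body_structure
腕	body_structure
手臂	body_structure
前肢	body_structure
i 型	type_stage
ii 型	type_stage
iii 型	type_stage
i型	type_stage
ii型	type_stage
iii型	type_stage
1型	type_stage
2型	type_stage
急性	type_stage
慢性	type_stage
无	negation
非	negation
不伴	negation
轻度	degree_adverb
中度	degree_adverb
重度	degree_adverb
左侧	laterality_position
右侧	laterality_position
双侧	laterality_position
小儿	age_group
老年	age_group
新生儿	age_group
病毒性	pathogen_etiology
细菌性	pathogen_etiology
真菌性	pathogen_etiology
过敏性	pathogen_etiology
复发性	temporal_course
持续性	temporal_course
结节性	morphology
弥漫性	morphology
男性	sex
女性	sex
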