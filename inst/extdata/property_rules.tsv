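rule_id	category	expression	context_keywords	needs_context	priority
dosage_per_admin	dosage	一[次日]\s*[0-9一二三四五六七八九十半]+(\.[0-9]+)?\s*[片粒克袋支丸]		0	10
dosage_per_weight	dosage	[0-9]+(\.[0-9]+)?\s*([-~－–][0-9]+(\.[0-9]+)?)?\s*(毫克|mg|克|g)\s*/\s*kg(体重)?		0	20
dosage_amount	dosage	[0-9一二三四五六七八九十半]+(\.[0-9]+)?\s*([-~－–][0-9]+(\.[0-9]+)?)?\s*(毫克|毫升|克|mg|ml|g)(/次)?	一次|每次|服用|用量|口服	1	30
frequency_daily	frequency	一日\s*[0-9一二三四五六七八九十]+\s*次		0	40
frequency_count	frequency	[0-9一二三四五六七八九十]+\s*次	一日|每日|每天|一天|分	1	50
duration_course	duration	疗程\s*[0-9一二三四五六七八九十]+\s*[日天]		0	60
duration_consecutive	duration	连续\s*[0-9]+(\.[0-9]+)?\s*([-~－–][0-9]+(\.[0-9]+)?)?\s*[日天]		0	70
duration_days	duration	[0-9]+(\.[0-9]+)?\s*([-~－–][0-9]+(\.[0-9]+)?)?\s*[日天]	疗程|持续|服用	1	80
population_age	population	[0-9一二三四五六七八九十]+\s*岁(以[上下])?		0	90
population_group	population	成人|儿童|小儿|老人|老年人|婴儿|新生儿|孕妇		0	100
usage_oral	usage	[口嚼吞泡饮]服		0	110
usage_iv	usage	静脉.{0,2}注射		0	120
usage_other	usage	外用|外涂|肛门用药|皮下注射|肌肉注射|静脉滴注		0	130
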