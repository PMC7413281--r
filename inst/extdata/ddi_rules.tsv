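rule_id	category	expression	priority	description
ddi_prohibit_combined	contraindication	禁止.*合用	10	sentence contains 禁止 and 合用
ddi_incompatible	contraindication	配伍禁忌	20	sentence contains 配伍禁忌
ddi_interfere	contraindication	干扰.*作用	30	sentence contains 干扰 and 作用
ddi_enhance_effect	promotion	加强.*效果	40	sentence contains 加强 and 效果
ddi_enhance_efficacy	promotion	增强.*疗效	50	sentence contains 增强 and 疗效
ddi_no_interaction	none	无相互作用	60	sentence contains 无相互作用
ddi_unchanged_action	none	不改变.*作用	70	sentence contains 不改变 and 作用
ddi_forbidden	contraindication	禁忌	80	sentence contains 禁忌
ddi_combined_risk	contraindication	合用.*(危险|不良反应|风险)	90	combined use stated to raise risk
ddi_unchanged	none	不改变|无影响|不受影响	100	combined use stated to change nothing
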