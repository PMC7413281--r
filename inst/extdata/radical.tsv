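char	value
病	疒
症	疒
疲	疒
瘀	疒
疗	疒
疹	疒
痛	疒
疮	疒
肝	月
肺	月
肠	月
肾	月
脑	月
背	月
膝	月
肘	月
腕	月
脱	月
洛	氵
沙	氵
湿	氵
汀	氵
法	氵
汗	氵
滞	氵
泥	氵
擦	扌
挫	扌
扭	扌
损	扌
苯	艹
苹	艹
糖	米
林	木
枫	木
柄	木
本	木
朵	木
恼	忄
心	忄
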