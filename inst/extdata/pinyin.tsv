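char	value
糖	tang
唐	tang
肝	gan
甘	gan
肺	fei
费	fei
心	xin
辛	xin
新	xin
胃	wei
未	wei
韦	wei
伟	wei
位	wei
肠	chang
常	chang
肾	shen
甚	shen
脑	nao
恼	nao
血	xue
雪	xue
骨	gu
古	gu
皮	pi
疲	pi
目	mu
木	mu
风	feng
枫	feng
热	re
寒	han
汗	han
湿	shi
诗	shi
瘀	yu
郁	yu
亏	kui
滞	zhi
志	zhi
病	bing
柄	bing
炎	yan
盐	yan
症	zheng
正	zheng
尿	niao
氨	an
安	an
苯	ben
本	ben
地	di
第	di
平	ping
苹	ping
洛	luo
落	luo
伐	fa
法	fa
他	ta
它	ta
汀	ting
厅	ting
西	xi
希	xi
膝	xi
林	lin
临	lin
沙	sha
纱	sha
星	xing
兴	xing
康	kang
慷	kang
唑	zuo
坐	zuo
米	mi
密	mi
多	duo
朵	duo
尼	ni
泥	ni
布	bu
步	bu
部	bu
手	shou
足	zu
头	tou
肩	jian
腰	yao
颈	jing
背	bei
肘	zhou
腕	wan
擦	ca
挫	cuo
扭	niu
脱	tuo
劳	lao
损	sun
伤	shang
型	xing
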