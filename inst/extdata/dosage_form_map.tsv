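form	usage
缓释片	口服
肠溶片	口服
直肠栓剂	肛门用药
贴剂	外用
洗剂	外用
片剂	口服
胶囊	口服
颗粒剂	口服
口服液	口服
软膏	外用
乳膏	外用
注射液	注射
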