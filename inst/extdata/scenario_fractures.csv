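type,year,without_denosumab,with_denosumab,saving_eur
hip,2010,36343,36343,NA
hip,2011,37142,37049,860000
hip,2012,37971,37808,2042000
hip,2013,38657,38382,3788000
vertebral,2010,21487,21487,NA
vertebral,2011,21506,21370,333000
vertebral,2012,21612,21387,653000
vertebral,2013,21640,21268,1139000
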