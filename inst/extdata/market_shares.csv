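product,year,share
denosumab,2010,0.000
denosumab,2011,0.023
denosumab,2012,0.052
denosumab,2013,0.080
alendronate_branded,2010,0.097
alendronate_branded,2011,0.086
alendronate_branded,2012,0.082
alendronate_branded,2013,0.077
alendronate_cholecalciferol,2010,0.159
alendronate_cholecalciferol,2011,0.154
alendronate_cholecalciferol,2012,0.142
alendronate_cholecalciferol,2013,0.137
alendronate_generic,2010,0.277
alendronate_generic,2011,0.273
alendronate_generic,2012,0.274
alendronate_generic,2013,0.270
risedronate,2010,0.243
risedronate,2011,0.246
risedronate,2012,0.244
risedronate,2013,0.243
zoledronate_branded,2010,0.003
zoledronate_branded,2011,0.004
zoledronate_branded,2012,0.004
zoledronate_branded,2013,0.004
ibandronate,2010,0.093
ibandronate,2011,0.090
ibandronate,2012,0.083
ibandronate,2013,0.079
raloxifene,2010,0.017
raloxifene,2011,0.017
raloxifene,2012,0.017
raloxifene,2013,0.017
strontium_ranelate,2010,0.098
strontium_ranelate,2011,0.093
strontium_ranelate,2012,0.089
strontium_ranelate,2013,0.081
calcitonin,2010,0.002
calcitonin,2011,0.002
calcitonin,2012,0.001
calcitonin,2013,0.001
teriparatide,2010,0.009
teriparatide,2011,0.009
teriparatide,2012,0.009
teriparatide,2013,0.009
pth,2010,0.002
pth,2011,0.002
pth,2012,0.002
pth,2013,0.002
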