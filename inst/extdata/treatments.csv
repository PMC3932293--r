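product,display_name,rrr_hip,rrr_vertebral,rrr_other,compliance,annual_cost_eur,duration_years,offset_years
denosumab,Denosumab,0.40,0.68,0.20,0.85,427,5,1
alendronate_branded,Fosamax,0.38,0.44,0.17,0.60,110,5,1
alendronate_cholecalciferol,Fosavance,0.38,0.44,0.17,0.60,118,5,1
alendronate_generic,Generic alendronate,0.38,0.44,0.17,0.60,100,5,1
risedronate,Actonel,0.26,0.36,0.25,0.60,122,5,1
zoledronate_generic,Generic zoledronate,0.41,0.70,0.24,0.60,180,5,1
zoledronate_branded,Aclasta,0.41,0.70,0.24,1.00,460,5,1
ibandronate,Bonviva,0.00,0.49,0.00,0.60,218,5,1
raloxifene,Evista,0.00,0.36,0.10,0.60,154,5,1
strontium_ranelate,Protelos,0.15,0.38,0.09,0.60,325,5,1
calcitonin,Miacalcic,0.00,0.00,0.00,0.60,90,5,1
teriparatide,Teriparatide,0.75,0.65,0.60,0.60,2300,2,1
pth,PTH 1-84,0.35,0.61,0.03,0.60,2100,2,1
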