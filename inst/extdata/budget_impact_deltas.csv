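category,year,delta_thousand_eur
medications,2011,-3766
medications,2012,-5854
medications,2013,-9385
inpatient,2011,-1174
inpatient,2012,-2025
inpatient,2013,-3383
outpatient,2011,-250
outpatient,2012,-420
outpatient,2013,-689
community,2011,0
community,2012,-624
community,2013,-1447
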