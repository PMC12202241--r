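dimension,level,decrement
intercept,0,1
AD,2,-0.060200000000000004
AD,3,-0.13545
AD,4,-0.22575
AD,5,-0.301
MO,2,-0.08000000000000002
MO,3,-0.18000000000000002
MO,4,-0.30000000000000004
MO,5,-0.4
PD,2,-0.072
PD,3,-0.162
PD,4,-0.27
PD,5,-0.36
SC,2,-0.06
SC,3,-0.135
SC,4,-0.22499999999999998
SC,5,-0.3
UA,2,-0.06
UA,3,-0.135
UA,4,-0.22499999999999998
UA,5,-0.3
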