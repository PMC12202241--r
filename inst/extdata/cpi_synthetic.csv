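year,index
2015,100
2016,100.5
2017,102
2018,103.8
2019,105.3
2020,105.8
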