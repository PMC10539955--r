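sample_id,replicate,m360,m361,m362
fed_1,1,755313,202559.3,41981.2
fed_1,2,755680.5,202515.2,42051.2
fed_1,3,755955.6,202438,42041.4
dex_1,1,705873.3,239312.4,55030.9
dex_1,2,707019.5,239410.1,55157.5
dex_1,3,706328.1,239198,55125.2
fasted_1,1,637881.1,288850.7,72754.3
fasted_1,2,638236.3,288352,72823.2
fasted_1,3,638807.1,289146,72759.6
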