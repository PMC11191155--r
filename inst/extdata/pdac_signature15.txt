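ABCC9
AP1M2
CAPN5
ITK
MPDZ
RCSD1
TMPRSS4
ABCA8
ELMO3
C1R
CELF2
IL7R
TTYH2
CD37
ZFP82
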