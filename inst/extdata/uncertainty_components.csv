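analyte,u1,u2,u3,u4
"2,4-D",0.0015,0.0302,0.0035,0.0298
carbendazim,0.0015,0.0205,0.0048,0.0213
thiabendazole,0.0015,0.0232,0.0045,0.0303
iprodione,0.0021,0.0027,0.0027,0.0371
prochloraz,0.0015,0.0285,0.0059,0.0306
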