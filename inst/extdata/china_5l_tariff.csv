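dimension,level,decrement
mo,1,0
mo,2,0.063
mo,3,0.111
mo,4,0.247
mo,5,0.343
sc,1,0
sc,2,0.052
sc,3,0.092
sc,4,0.255
sc,5,0.281
ua,1,0
ua,2,0.049
ua,3,0.076
ua,4,0.152
ua,5,0.200
pd,1,0
pd,2,0.046
pd,3,0.081
pd,4,0.201
pd,5,0.244
ad,1,0
ad,2,0.059
ad,3,0.090
ad,4,0.250
ad,5,0.323
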