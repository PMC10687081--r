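stage,base_age,top_age
Lochkovian,419.2,410.8
Pragian,410.8,407.6
Emsian,407.6,393.3
Eifelian,393.3,387.7
Givetian,387.7,382.7
Frasnian,382.7,372.2
Famennian,372.2,358.9
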