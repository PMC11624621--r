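variant_id,scaffold,position,impact_score,sex_linked
v1,scafA,100,5,FALSE
v2,scafA,200,7,FALSE
v3,scafB,50,10,FALSE
v4,scafB,150,3,FALSE
v5,scafB,250,4,FALSE
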