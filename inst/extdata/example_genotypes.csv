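variant_id,PP1,PP2,PP3
v1,2,0,0
v2,1,1,0
v3,0,2,0
v4,1,0,2
v5,1,1,0
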