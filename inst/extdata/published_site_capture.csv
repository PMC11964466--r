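"phase","dataset","n_inside","n_total"
"GI1DA","A",1220,1356
"GS1","A",825,1003
"GI1DA","B",842,988
"GS1","B",415,560
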