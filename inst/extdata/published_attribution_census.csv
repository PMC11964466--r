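"flag","n_assemblages"
"GI1DA",988
"GS1",560
"FP_GENERIC",237
"FP_PB_GENERIC",131
"GS1_PB",75
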