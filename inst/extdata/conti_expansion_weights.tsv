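marker_id	Multi	European	African	Asian	Hispanic
rsPAIR001	0.0187508038332883	0.0133361794920993	0.107552929678819	-0.113430547685093	-0.146439072996638
rsPAIR002	0.148132240847573	0.0213222920964953	0.0325369994989838	-0.0826253052899571	0.164959112141643
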