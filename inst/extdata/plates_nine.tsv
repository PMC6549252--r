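name	plate
SolV	Eurasian
Fur	Eurasian
Rib	Eurasian
Fdl	Eurasian
Ice	Eurasian
Yel	North American
Phi	Philippine-boundary
V4	Australian-Pacific
Kam1	Okhotsk
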