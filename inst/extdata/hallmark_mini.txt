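g0001
g0002
g0004
g0007
g0010
g0011
g0014
g0018
g0019
g0023
g0025
g0026
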