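X:1
T:ExampleAmbient
M:4/4
L:1/16
Q:1/4=70
K:C
E4 G4 z2 C2 | D2 E2 z4 G4 | z4 E4 C4
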