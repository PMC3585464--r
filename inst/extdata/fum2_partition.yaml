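'Y':
- F
- H
- OH
- M
- d1
- d2
- d3
- d4
- d5
- d6
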