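'Y':
- E
- EF
- EH
- EFH
- EM
frozen:
- F
- H
- OH
- M
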