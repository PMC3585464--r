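# Hansen mechanism for malate synthesis by fumarase: the enzyme binds
# fumarate (F) and hydrogen (H) in either order, then hydroxyl (OH),
# followed by reversible formation of malate (M). All steps reversible.
species: E EF EH EFH EM F H OH M
E + F <-> EF    ; a1, d1
E + H <-> EH    ; a2, d2
EF + H <-> EFH  ; a3, d3
EH + F <-> EFH  ; a4, d4
EFH + OH <-> EM ; a5, d5
EM <-> E + M    ; d6, a6
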