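# open Michaelis-Menten system: enzyme catalysis with substrate synthesis
# and product degradation, so a non-trivial steady state exists
E + S -> ES ; k1
ES -> E + S ; k2
ES -> E + P ; k3
Ø -> S ; k4
P -> Ø ; k5
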