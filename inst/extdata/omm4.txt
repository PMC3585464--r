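# open Michaelis-Menten variant with catalysis proportional to the square of
# the enzyme-substrate complex
E + S -> ES ; k1
ES -> E + S ; k2
ES -> E + P ; k3 ; order(ES) = 2
Ø -> S ; k4
P -> Ø ; k5
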