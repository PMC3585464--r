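# two-species positive-feedback switch: signal S drives autocatalytic
# production of A (second order in A), with first-order decay and a
# third-order sink that bounds the induced state
Ø -> S ; ks
S -> Ø ; kds
Ø -> A ; k0
S + A -> S + 2 A ; kf ; order(A) = 2
A -> Ø ; kda
3 A -> 2 A ; kc
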