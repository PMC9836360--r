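# Default wobble selective-constraint vector (s-vector).
# Values are the widely used defaults of the reference tRNA adaptation
# index implementation; edit and load with read_s_vector().
# WC = Watson-Crick 34:3 pairings (including A34:U3).
# G:U = G34 reading U-ending codons; U:G = U34 reading G-ending codons;
# I:C / I:A = A34 treated as inosine reading C- / A-ending codons.
class	s
WC	0
G:U	0.41
I:C	0.28
I:A	0.9999
U:G	0.68
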