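LOCUS       SYNMITO01                 70 bp    DNA     circular
DEFINITION  Synthetic mitogenome fixture (hand-built, not a real genome).
FEATURES             Location/Qualifiers
     source          1..70
     CDS             4..12
                     /gene="atp8"
     CDS             complement(20..28)
                     /gene="cob"
     CDS             join(31..36,
                     40..45)
                     /gene="nad1"
     CDS             complement(join(50..55,60..65))
                     /gene="cox1"
     tRNA            3..5
                     /product="tRNA-Ala"
                     /anticodon="(pos:3..5,aa:Ala,seq:ugc)"
     tRNA            6..8
                     /product="tRNA-Ala"
                     /anticodon="(pos:6..8,aa:Ala,seq:ugc)"
     tRNA            9..11
                     /product="tRNA-Ile"
                     /note="anticodon: GAU"
     tRNA            13..15
                     /product="tRNA-Ser"
     rRNA            66..70
                     /product="rnl"
ORIGIN
        1 aaaatggcag catttttttt gctgccatcc atggcagggg cataattttt taccaggggt
       61 gccataaaaa
//
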