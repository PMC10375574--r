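name	sequence
gRNA_X	C(ms)A(ms)G(ms)GUUCCAUGGGAUGCUCUG(m)UUUUAGA(m)G(m)C(m)U(m)A(m)G(m)A(m)A(m)A(m)U(m)A(m)G(m)C(m)A(m)A(m)GUUA(m)AA(m)AU(m)AA(m)G(m)G(m)C(m)U(m)A(m)GUC(m)C(m)GUUAU(m)C(m)AAC(m)U(m)U(m)G(m)A(m)A(m)A(m)A(m)A(m)G(m)U(m)G(m)GC(m)A(m)C(m)C(m)G(m)A(m)G(m)U(m)C(m)G(m)G(m)U(m)G(m)C(m)U(ms)U(ms)U(ms)U(m)
gRNA_XA	C(ms)U(ms)G(ms)GUUCCAUGGGAUGCUCUG(m)UUUUAGA(m)G(m)C(m)U(m)A(m)G(m)A(m)A(m)A(m)U(m)A(m)G(m)C(m)A(m)A(m)GUUA(m)AA(m)AU(m)AA(m)G(m)G(m)C(m)U(m)A(m)GUC(m)C(m)GUUAU(m)C(m)AAC(m)U(m)U(m)G(m)A(m)A(m)A(m)A(m)A(m)G(m)U(m)G(m)GC(m)A(m)C(m)C(m)G(m)A(m)G(m)U(m)C(m)G(m)G(m)U(m)G(m)C(m)U(ms)U(ms)U(ms)U(m)
gRNA_XB	C(ms)A(ms)G(ms)GUUCCAUAGGAUGCUCUG(m)UUUUAGA(m)G(m)C(m)U(m)A(m)G(m)A(m)A(m)A(m)U(m)A(m)G(m)C(m)A(m)A(m)GUUA(m)AA(m)AU(m)AA(m)G(m)G(m)C(m)U(m)A(m)GUC(m)C(m)GUUAU(m)C(m)AAC(m)U(m)U(m)G(m)A(m)A(m)A(m)A(m)A(m)G(m)U(m)G(m)GC(m)A(m)C(m)C(m)G(m)A(m)G(m)U(m)C(m)G(m)G(m)U(m)G(m)C(m)U(ms)U(ms)U(ms)U(m)
gRNA_XC	C(ms)A(ms)G(ms)GUUCCAUGGGAUGCUCGG(m)UUUUAGA(m)G(m)C(m)U(m)A(m)G(m)A(m)A(m)A(m)U(m)A(m)G(m)C(m)A(m)A(m)GUUA(m)AA(m)AU(m)AA(m)G(m)G(m)C(m)U(m)A(m)GUC(m)C(m)GUUAU(m)C(m)AAC(m)U(m)U(m)G(m)A(m)A(m)A(m)A(m)A(m)G(m)U(m)G(m)GC(m)A(m)C(m)C(m)G(m)A(m)G(m)U(m)C(m)G(m)G(m)U(m)G(m)C(m)U(ms)U(ms)U(ms)U(m)
gRNA_XD	C(ms)A(ms)G(ms)GCUCCAUGGGAUGCUCUG(m)UUUUAGA(m)G(m)C(m)U(m)A(m)G(m)A(m)A(m)A(m)U(m)A(m)G(m)C(m)A(m)A(m)GUUA(m)AA(m)AU(m)AA(m)G(m)G(m)C(m)U(m)A(m)GUC(m)C(m)GUUAU(m)C(m)AAC(m)U(m)U(m)G(m)A(m)A(m)A(m)A(m)A(m)G(m)U(m)G(m)GC(m)A(m)C(m)C(m)G(m)A(m)G(m)U(m)C(m)G(m)G(m)U(m)G(m)C(m)U(ms)U(ms)U(ms)U(m)
gRNA_Y	C(ms)C(ms)C(ms)GCUCGUUAACGCAACGGG(m)UUUUAGA(m)G(m)C(m)U(m)A(m)GA(m)A(m)A(m)U(m)A(m)G(m)C(m)A(m)A(m)GUUA(m)AA(m)AU(m)AA(m)G(m)G(m)C(m)U(m)A(m)GUC(m)C(m)GUUAU(m)C(m)AAC(m)U(m)U(m)GA(m)A(m)A(m)A(m)A(m)G(m)U(m)G(m)GC(m)A(m)C(m)C(m)G(m)A(m)G(m)U(m)C(m)G(m)G(m)U(m)G(m)C(m)U(ms)U(ms)U(ms)U(m)
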