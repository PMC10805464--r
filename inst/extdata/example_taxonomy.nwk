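(((OTU1,OTU2,OTU3)g_Prevotella,(OTU4,OTU5)g_Bacteroides)f_Bacteroidaceae,((OTU6,OTU7)g_Blautia,OTU8)f_Lachnospiraceae)k_Bacteria;
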