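>synthetic_fg_domain_156
NTGAAGQSTTGLFGGSQAGSGFGGSAGGGFGSNGASGGANAFGQGGNAGQFGTNNQTGFG
GGGSGGGNSQFGSNGSGQASNFGSSTSGSGGSGFGQSTQSGGLFGTQQQGATGGAFGNTS
NSGQGLFGSNTQGSGLFGTSSNNSSSGLFGQSNSQG
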