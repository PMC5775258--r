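>TRPA1_1 acceptor T101
YGNTPLHCAA
>TRPA1_2 acceptor S134
NMMSPLHIAV
>TRPA1_3 acceptor S242
KKASPLHLAV
>TRPA1_4 acceptor T416
DGCTPLHYAC
>TRPA1_5 acceptor S449
DKKSPLHFAA
>TRPA1_6 acceptor T485
HGMTPLHLAA
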