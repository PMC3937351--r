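its1	0	200
r58s	200	364
its2	364	560
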