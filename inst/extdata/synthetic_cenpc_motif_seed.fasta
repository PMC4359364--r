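>cenpc_motif_seed_1
WTRRVSEFLEDPQVRGNIKWHEDG
>cenpc_motif_seed_2
WTRRVSEFLEDPFVSGNIKWHEDG
>cenpc_motif_seed_3
WTRRVSEFCEDPQVRGNIKWHEDG
>cenpc_motif_seed_4
STRRVSEFLEDPQVRGNIKWHEDG
>cenpc_motif_seed_5
WTRRVSEFLEHPQVRGNIKWHEDG
>cenpc_motif_seed_6
WTRRVSEFLEDPQVRGNIKWHEHG
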