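##gff-version 3
##source-version rtracklayer 1.62.0
##date 2026-09-24
ctg_L0001	rtracklayer	gene	583	882	.	+	.
ctg_L0002	rtracklayer	gene	856	1155	.	+	.
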