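file	rows
pairs.genome	30
pairs.tsv	30
config.json	NA
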