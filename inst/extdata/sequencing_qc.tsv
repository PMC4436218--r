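library	total_ends	paired_reads	unique_reads
invivo	49750000	20390000	16590000
invitro	70170000	29850000	25290000
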