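map_version	immunoseq	airr
1	nucleotide	junction
1	aminoAcid	junction_aa
1	vGeneName	v_call
1	jGeneName	j_call
1	count (templates/reads)	duplicate_count
1	count	duplicate_count
1	templates	duplicate_count
1	sequenceStatus	productive
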