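name	file	md5
eisenberg	eisenberg.tsv	257de5a90c94eceda0a8c264462726eb
gpcrtm	gpcrtm_synthetic.tsv	63ac34dbfe2ba2312ca0a7bf167dbfd9
orthosteric24	orthosteric24.tsv	276d5b2f582f2ffb2fb398304edecb55
or_important11	or_important11.tsv	6c4e187db557912d3ee53a4106fc5791
known_or1a2_ligands	known_or1a2_ligands_synthetic.tsv	12d711f6db5b96dd00c1d5b570cbf764
mmgbsa_reference	mmgbsa_reference_components.csv	2227deb0d46085ef74c2a3d0aa382a56
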