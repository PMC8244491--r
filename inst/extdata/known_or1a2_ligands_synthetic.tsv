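# Known-OR1A2-ligand manifest: 3 literature entries + 10 SYNTHETIC
# placeholders standing in for the unavailable published list of 13.
# version: 0-partial-synthetic
name	pubchem_cid	smiles	provenance
(S)-(-)-citronellal	7794	CC(CCC=C(C)C)CC=O	literature
helional	91497	CC(Cc1ccc2c(c1)OCO2)C=O	literature
octanal	454	CCCCCCCC=O	literature
synthetic_terpenoid_01	NA	CC(CCC=C(C)C)CO	synthetic
synthetic_terpenoid_02	NA	CC(CCCC(C)C)CC=O	synthetic
synthetic_terpenoid_03	NA	CC(CCC=C(C)C)C=O	synthetic
synthetic_terpenoid_04	NA	CC(C)=CCCC(C)CCO	synthetic
synthetic_aldehyde_05	NA	CCCCCCC=O	synthetic
synthetic_aldehyde_06	NA	CCCCCCCCC=O	synthetic
synthetic_terpenoid_07	NA	CC(C)=CCCC(C)=CC=O	synthetic
synthetic_alcohol_08	NA	CCCCCCCCO	synthetic
synthetic_terpenoid_09	NA	CC(CCC=C(C)C)CCO	synthetic
synthetic_terpenoid_10	NA	CC(C)=CCCC(C)CC=O	synthetic
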