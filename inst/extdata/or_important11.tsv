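# Olfactory-receptor-important orthosteric positions (mutagenesis)
# version: 1.0
bw_position
3.33
3.36
3.37
5.43
5.47
6.48
6.51
6.52
6.55
7.41
7.42
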