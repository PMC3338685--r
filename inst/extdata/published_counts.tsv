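quantity	value
nSSRs	4249
nTranscriptsSearched	196708
totalSearchedBp	46830000
nSSRTranscripts	4028
nCompoundSSRs	129
nLibraries	7
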