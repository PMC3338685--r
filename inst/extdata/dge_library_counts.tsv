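row	YL	ML	Stem	FR	ITR	ETR	HTR
rawTags	3536026	3630797	3616244	3847265	3823315	3711657	3745496
cleanTags	3352753	3429018	3453654	3583907	3630619	3566630	3541272
distinctRawTags	307858	302173	280858	384868	280755	237874	299486
distinctCleanTags	125145	118397	118715	139389	109697	93593	115636
mappedCleanTags	2506655	2894248	2904513	2890484	3177381	3101355	2764216
mappedDistinctCleanTags	69118	76860	75256	81687	74598	60619	68341
unambiguousCleanTags	2154554	2529417	2551795	2504573	2760652	2699212	2363845
unambiguousDistinctCleanTags	51109	56449	57232	59107	54378	43755	49798
tagMappedTranscripts	30977	32131	33754	35109	32900	28645	30730
unambiguousTagMappedTranscripts	25558	26717	28013	29162	27244	23490	25309
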