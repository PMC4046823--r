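label	n_peaks_total	n_peaks_promoter	n_tfbs_peaks_total	n_tfbs_peaks_promoter	n_tfbs_total	n_tfbs_promoter
M	53972	10282	15428	3934	110779	27615
C	32158	12069	7153	4640	30828	5322
T	459962	37923	99986	20735	477353	20008
B	241257	35349	102905	9188	220182	48710
M+C+T	465103	31096	100484	15352	460753	39449
M+T	460503	38023	100417	20775	477996	22042
M+C	65605	32588	17643	7400	120964	54569
C+T	462622	43355	100284	20735	478565	22008
M*C*T	20349	9834	4834	3604	20525	3860
M*T	50655	17246	15274	9312	128473	10526
M*C	20525	9852	4863	3612	20643	3874
C*T	30158	11914	6780	4637	29616	4956
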