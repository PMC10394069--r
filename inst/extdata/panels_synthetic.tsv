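haplogroup	parent	position	ref	alt	class
T123	NA	2536	A	G	transition
T123	NA	4021	C	T	transition
T123	NA	9682	G	A	transition
T1	T123	1119	C	T	transition
T1	T123	5267	G	A	transition
T1	T123	8154	A	G	transition
T1	T123	12789	T	C	transition
T3	T123	3310	G	A	transition
T3	T123	6890	C	T	transition
T3	T123	10433	T	C	transition
T3	T123	13904	A	G	transition
T1a	T1	2210	T	C	transition
T1a	T1	11561	G	A	transition
T1b	T1	7542	C	T	transition
T1b	T1	16022	C	T	transition
T1d	T1	4875	A	G	transition
T1d	T1	14300	C	T	transition
I	NA	640	C	A	transversion
I	NA	7015	A	G	transition
I	NA	15010	G	A	transition
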