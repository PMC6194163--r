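position	ref	alt	label	syndrome
3243	A	G	m.3243A>G	MELAS/MIDD
8344	A	G	m.8344A>G	MERRF
8993	T	G	m.8993T>G	NARP/Leigh
11778	G	A	m.11778G>A	LHON
13513	G	A	m.13513G>A	Leigh
14484	T	C	m.14484T>C	LHON
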