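# Published fine-mapping result at the APOH locus for total anti-b2GPI
# antibody levels: the 95% credible set (single set, 18 variants) with
# per-variant posterior inclusion probabilities, as printed.
variant_id	chromosome	position	effect_allele	other_allele	eaf	pip	annotation	nearest_gene
rs1801690	17	66212167	G	C	0.05	0.49	exonic	APOH
rs9902706	17	66190870	T	C	0.06	0.06	intronic	CEP112
rs9906486	17	66194802	T	G	0.06	0.05	intergenic	CEP112
rs9905408	17	66194566	C	A	0.06	0.04	intergenic	CEP112
rs7211380	17	66210650	G	A	0.06	0.04	intergenic	APOH
rs74934196	17	66154754	A	AAC	0.05	0.03	intronic	CEP112
rs74531840	17	66179997	A	T	0.05	0.03	intronic	CEP112
rs76375367	17	66142666	A	G	0.06	0.02	intronic	CEP112
rs55657678	17	66144550	A	G	0.06	0.02	intronic	CEP112
rs11651658	17	66202522	C	T	0.06	0.02	intergenic	APOH
rs73992250	17	66136049	G	A	0.06	0.02	intronic	CEP112
rs7216660	17	66151258	T	C	0.06	0.02	intronic	CEP112
rs9891968	17	66136728	A	G	0.06	0.02	intronic	CEP112
rs9908597	17	66138565	G	T	0.06	0.02	intronic	CEP112
rs9895407	17	66161737	C	T	0.06	0.02	intronic	CEP112
rs77620153	17	66134676	A	G	0.06	0.02	intronic	CEP112
rs73992258	17	66168965	C	A	0.06	0.02	intronic	CEP112
rs9911603	17	66135784	T	C	0.06	0.02	intronic	CEP112
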