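reaction_id	gene_family	compound	coefficient	reversible
R00001	K00001	C00022	-1	false
R00001	K00001	C00186	1	false
R00002	K00016	C00022	1	false
R00002	K00016	C00186	-1	false
R00004	K00128	C00084	-1	false
R00004	K00128	C00033	1	false
R00006	K01568	C00022	-1	false
R00006	K01568	C00084	1	false
R00014	K00627	C00022	-1	false
R00014	K00627	C00024	1	false
R00026	K01187	C00208	-1	false
R00026	K01187	C00031	2	false
R00031	K00688	C00103	1	false
R00031	K00688	C00031	-1	false
R00036	K01667	C00082	-1	false
R00036	K01667	C00022	1	false
R00045	K00260	C00025	-1	false
R00045	K00260	C00026	1	false
R00051	K01580	C00025	-1	false
R00051	K01580	C00334	1	false
R00093	K00266	C00025	1	false
R00093	K00266	C00026	-1	false
R00112	K00324	C00004	-1	true
R00112	K00324	C00003	1	true
R00258	K00814	C00041	-1	false
R00258	K00814	C00022	1	false
R00369	K00830	C00041	1	false
R00369	K00830	C00022	-1	false
R01015	K01803	C00118	-1	true
R01015	K01803	C00111	1	true
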