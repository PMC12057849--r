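distance	nodes	edges	positive_edges	negative_edges	average_degree	average_path_length	network_diameter	network_density	clustering_coefficient
H0	241	1299	735	564	10.7801	3.8889	12	0.0449	0.5222
H1	240	1104	584	520	9.2000	5.1753	14	0.0385	0.5311
H2	240	567	417	150	4.7250	6.1269	15	0.0198	0.4764
H3	240	675	442	233	5.6250	6.4792	17	0.0235	0.5304
H5	237	653	351	302	5.5105	5.3874	14	0.0233	0.4437
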