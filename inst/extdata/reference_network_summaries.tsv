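network	nodes	edges	avg_degree_centrality	avg_betweenness_centrality
Antipsychotics	89	419	0.106	0.0157
Psychosis	486	1409	0.0119	0.00642
Psychosis-antipsychotics combined	570	1825	0.0112	0.00563
AD	1061	15691	0.0279	0.00167
AD-psychosis combined	1456	16989	0.0160	0.00158
Vitamin D	89	344	0.0869	0.018
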