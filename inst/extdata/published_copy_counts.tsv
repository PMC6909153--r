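species	class	display	published_count
Calvadosia cruxmelitensis	Staurozoa	RPRSamide	11
Haliclystus auricula	Staurozoa	RPRSamide	15
Haliclystus sanjuanensis	Staurozoa	RPRSamide	16
Craterolophus convolvulus	Staurozoa	RPRSamide	8
Lucernaria quadricornis	Staurozoa	RPRSamide	3
Lucernaria quadricornis	Staurozoa	KPRSamide	6
Renilla reniformis	Octocorallia	GPRRamide	2
Eleutherobia rubra	Octocorallia	GPRRamide	8
Xenia sp.	Octocorallia	GPRRamide	15
Briareum asbestinum	Octocorallia	GPRRamide	22
Clavularia sp.	Octocorallia	GPRRamide	5
Heliopora coerulea	Octocorallia	GPRRamide	4
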