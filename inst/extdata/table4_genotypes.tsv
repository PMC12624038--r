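CHROM	POS	Albatros	Arborio	Arelate	Ariete	Basmati Type III	Bomba	CL-28	Caravela	Carnaroli	Elettra	Gageron	Giza 177	Giza 181	JSendra	Lusitano	Maçarico	Manobi	Puntal	Ronaldo	Super Basmati	Teti	Ulisse
4	22375729	0/0	1/1	0/0	1/1	1/1	0/0	0/0	1/1	1/1	0/0	1/1	1/1	1/1	0/0	1/1	1/1	0/0	1/1	1/1	1/1	0/0	1/1
6	20640731	0/0	1/1	0/0	0/0	0/1	1/1	0/0	0/0	1/1	1/1	0/0	0/0	0/0	1/1	0/1	1/1	1/1	0/0	0/0	0/0	1/1	0/1
10	6918411	0/0	1/1	0/0	0/0	1/1	0/0	1/1	1/1	0/0	1/1	0/0	0/0	1/1	0/0	1/1	0/1	0/0	0/1	0/1	1/1	1/1	1/1
11	19577767	1/1	1/1	1/1	0/0	0/0	1/1	1/1	0/0	1/1	1/1	0/0	1/1	1/1	0/0	0/1	1/1	0/0	1/1	0/1	0/0	1/1	1/1
11	28814241	0/1	0/1	0/0	0/1	0/1	0/0	0/0	0/1	0/1	0/0	0/0	0/0	0/0	0/1	0/1	0/0	0/0	0/1	0/1	0/0	0/1	0/1
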