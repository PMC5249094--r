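variant_id	gene	chrom	pos	cdna	protein	polyphen2	provean	sift
SLC35E3:c.1363A>C	SLC35E3	10	10905842	c.1363A>C	p.R145S	0.001	-0.404	0.400
ENSCAFG00000029271:c.130G>A	ENSCAFG00000029271	10	23266184	c.130G>A	p.K44E	0.617	-1.000	0.320
L3MBTL2:c.2711A>G	L3MBTL2	10	24002628	c.2711A>G	p.R675Q	0.000	-0.263	1.000
XPNPEP3:c.725G>A	XPNPEP3	10	24347707	c.725G>A	p.H242R	0.003	-1.239	0.290
PDGFB_CANFA:c.693C>A	PDGFB_CANFA	10	25817180	c.693C>A	p.E231D	0.048	-0.740	0.030
PLA2G6:c.1516G>A	PLA2G6	10	26544757	c.1516G>A	p.I506V	0.000	-0.437	0.190
PLA2G6:c.1579G>A	PLA2G6	10	26544820	c.1579G>A	p.T527A	0.201	-2.403	0.010
CCDC66:c.2024T>C	CCDC66	20	33717816	c.2024T>C	p.T675M	0.011	-1.007	0.720
PGBD1:c.38G>A	PGBD1	35	25421942	c.38G>A	p.D13G	0.000	0.227	0.880
ZSCAN31:c.412G>A	ZSCAN31	35	25456698	c.412G>A	p.T138A	0.141	0.158	0.450
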