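chrom	start	end	region_id	Bcell	CD4T	CD8T	Gran	Mono	NK
chrSim	1300	1701	chrSim:1300-1701	1	1	1	0	1	1
chrSim	2100	2501	chrSim:2100-2501	0	0	0	1	0	0
chrSim	2900	3301	chrSim:2900-3301	1	1	1	0	1	1
chrSim	3700	4101	chrSim:3700-4101	0	0	0	1	0	0
chrSim	4500	4901	chrSim:4500-4901	1	0	1	1	1	1
chrSim	5300	5701	chrSim:5300-5701	0	1	0	0	0	0
chrSim	6100	6501	chrSim:6100-6501	1	0	1	1	1	1
chrSim	6900	7301	chrSim:6900-7301	0	1	0	0	0	0
chrSim	7700	8101	chrSim:7700-8101	1	1	0	1	1	1
chrSim	8500	8901	chrSim:8500-8901	0	0	1	0	0	0
chrSim	9300	9701	chrSim:9300-9701	1	1	0	1	1	1
chrSim	10100	10501	chrSim:10100-10501	0	0	1	0	0	0
chrSim	10900	11301	chrSim:10900-11301	0	1	1	1	1	1
chrSim	11700	12101	chrSim:11700-12101	1	0	0	0	0	0
chrSim	12500	12901	chrSim:12500-12901	0	1	1	1	1	1
chrSim	13300	13701	chrSim:13300-13701	1	0	0	0	0	0
chrSim	14100	14501	chrSim:14100-14501	1	1	1	1	0	1
chrSim	14900	15301	chrSim:14900-15301	0	0	0	0	1	0
chrSim	15700	16101	chrSim:15700-16101	1	1	1	1	0	1
chrSim	16500	16901	chrSim:16500-16901	0	0	0	0	1	0
chrSim	17300	17701	chrSim:17300-17701	1	1	1	1	1	0
chrSim	18100	18501	chrSim:18100-18501	0	0	0	0	0	1
chrSim	18900	19301	chrSim:18900-19301	1	1	1	1	1	0
chrSim	19700	20101	chrSim:19700-20101	0	0	0	0	0	1
chrSim	20500	20901	chrSim:20500-20901	0	0	0	0	0	0
chrSim	21300	21701	chrSim:21300-21701	1	1	1	1	1	1
chrSim	22100	22501	chrSim:22100-22501	0	0	0	0	0	0
chrSim	22900	23301	chrSim:22900-23301	1	1	1	1	1	1
chrSim	23700	24101	chrSim:23700-24101	0	0	0	0	0	0
chrSim	24500	24901	chrSim:24500-24901	1	1	1	1	1	1
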