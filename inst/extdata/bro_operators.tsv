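id	smirks	ec3	cofactors_in	cofactors_out	name
alcohol_ox_sec	[C:1][CH1:2]([OH1:3])[C:4]>>[C:1][C:2](=[O:3])[C:4]	1.1.1	acceptor_ox	acceptor_red	secondary alcohol -> ketone
alcohol_ox_prim	[C:1][CH2:2][OH1:3]>>[C:1][CH1:2]=[O:3]	1.1.1	acceptor_ox	acceptor_red	primary alcohol -> aldehyde
ketone_red	[C:1][C:2](=[O:3])[C:4]>>[C:1][CH1:2]([OH1:3])[C:4]	1.1.1	acceptor_red	acceptor_ox	ketone -> secondary alcohol
aldehyde_red	[C:1][CH1:2]=[O:3]>>[C:1][CH2:2][OH1:3]	1.1.1	acceptor_red	acceptor_ox	aldehyde -> primary alcohol
aldehyde_ox	[C:1][CH1:2]=[O:3]>>[C:1][C:2](=[O:3])[OH1]	1.2.1	water,acceptor_ox	acceptor_red	aldehyde -> carboxylic acid
alkene_hydration	[C:1]=[C:2]>>[C:1][C:2][OH1]	4.2.1	water	-	alkene hydration
dehydration	[C:1][C:2][OH1]>>[C:1]=[C:2]	4.2.1	-	water	alcohol dehydration
decarboxylation	[C:1]C(=O)[OH1]>>[C:1]	4.1.1	-	co2	carboxylic acid decarboxylation
reductive_amination	[C:1][C:2](=[O])[C:4]>>[C:1][CH1:2]([NH2])[C:4]	1.4.1	ammonia,acceptor_red	water,acceptor_ox	ketone reductive amination
oxidative_deamination	[C:1][CH1:2]([NH2])[C:4]>>[C:1][C:2](=[O])[C:4]	1.4.1	water,acceptor_ox	ammonia,acceptor_red	amine oxidative deamination
phosphorylation	[C:1][OH1:2]>>[C:1][O:2]P(=O)([OH1])[OH1]	2.7.1	phosphate	water	alcohol phosphorylation
hydroxylation	[C:1][CH2:2][C:3]>>[C:1][CH1:2]([OH1])[C:3]	1.14.13	o2,acceptor_red	water,acceptor_ox	methylene hydroxylation
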