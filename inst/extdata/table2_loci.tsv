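name	chrom	start	end	implicated_types	disorders
15q13.1-13.2	15	28962131	30369914	DUP	DD/ID
16p13.11	16	15493046	16251647	DEL,DUP	ADHD,ASD,DD/ID
16p12.2	16	21966869	22392905	DEL	DD/ID,SCZ
22q11.21	22	18892575	21460220	DEL,DUP	ADHD,ASD,DD/ID,SCZ,TD
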