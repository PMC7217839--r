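call_id	sample_id	chrom	start	end	locus	cnv_type	confidence	n_probes	size_printed	n_genes_printed
c01	T001	4	71566	1818625	4p16.3	DEL	234.04	465	1747059	36
c02	T002	4	66110165	66881057	4q13.1-13.2	DEL	379.84	512	770892	2
c03	T002	4	89020503	90256211	4q22.1	DUP	547.52	2352	1235708	11
c04	T003	10	48302618	51832220	10q11.22-11.23	DEL	1076.37	738	3529602	42
c05	T004	10	68626126	68875634	10q21.3	DEL	110.26	39	249508	1
c06	T005	10	75940906	76360232	10q22.2	DEL	19.32	522	419326	1
c07	T006	11	5653807	7482226	11p15.4	DEL	817.108	1198	1828419	52
c08	T007	15	28962131	30369914	15q13.1-13.2	DUP	295.84	3234	1407783	8
c09	T008	15	102165387	102398631	15q26.3	DEL	188.83	487	233244	5
c10	T009	16	6186577	6462231	16p13.3	DEL	186.71	850	275654	1
c11	T010	16	15493046	16251647	16p13.11	DUP	85.57	426	758601	9
c12	T011	16	21966869	22392905	16p12.2	DEL	181.716	144	426036	7
c13	T012	20	3090124	3891896	20p13	DEL	1115.83	407	801772	20
c14	T013	22	18892575	21460220	22q11.21	DUP	129.78	8824	2567645	67
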