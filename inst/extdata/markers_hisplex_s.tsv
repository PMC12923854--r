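rsid	chrom	pos_GRCh37	pos_GRCh38	ref	alt	probe_strand	counted_allele	variant_class	global_maf	trait_tags	may_be_absent_GRCh38
rs312262906	16	89985752	89919344	A	AA	forward	A	single-base-duplication	0.00078	mc1r,hair	FALSE
rs11547464	16	89986091	89919683	G	A	forward	A	SNP	0.008	mc1r,hair	FALSE
rs885479	16	89986154	89919746	G	A	reverse	T	SNP	0.183	mc1r,hair	FALSE
rs1805008	16	89986546	89920138	C	T	forward	T	SNP	0.014	mc1r,hair	FALSE
rs1805005	16	89985844	89919436	G	T	forward	T	SNP	0.051	mc1r,hair	FALSE
rs1805006	16	89985918	89919510	C	A	forward	A	SNP	0.005	mc1r,hair	FALSE
rs1805007	16	89986117	89919709	C	T	forward	T	SNP	0.036	mc1r,hair	FALSE
rs1805009	16	89986608	89920200	G	C	forward	C	SNP	0.008	mc1r,hair	FALSE
rs201326893	16	89986122	89919714	C	A	forward	A	SNP	0.001	mc1r,hair	TRUE
rs2228479	16	89985940	89919532	G	A	forward	A	SNP	0.0766	mc1r,hair	FALSE
rs1110400	16	89986130	89919722	T	C	forward	C	SNP	0.010	mc1r,hair	FALSE
rs28777	5	33958959	33958854	C	A	forward	C	SNP	0.23	hair,skin	FALSE
rs16891982	5	33951693	33951588	C	G	forward	C	SNP	0.30	eye,hair,skin	FALSE
rs12821256	12	89328335	88934558	T	C	reverse	G	SNP	0.11	hair	FALSE
rs4959270	6	457748	457748	C	A	forward	A	SNP	0.42	hair	FALSE
rs12203592	6	396321	396321	C	T	forward	T	SNP	0.10	eye,hair,skin	FALSE
rs1042602	11	88911696	89178528	C	A	forward	A	SNP	0.22	hair,skin	FALSE
rs1800407	15	28230318	27985172	G	A	forward	A	SNP	0.05	eye	FALSE
rs2402130	14	92801203	92334859	A	G	forward	G	SNP	0.33	hair	FALSE
rs12913832	15	28365618	28120472	A	G	reverse	T	SNP	0.26	eye,hair,skin	FALSE
rs2378249	20	33218090	34630286	A	G	forward	G	SNP	0.15	hair	FALSE
rs12896399	14	92773663	92307319	G	T	forward	T	SNP	0.44	eye,hair	FALSE
rs1393350	11	89011046	89277878	G	A	forward	A	SNP	0.21	eye,hair	FALSE
rs683	9	12709305	12709305	C	A	reverse	G	SNP	0.42	hair	FALSE
rs3114908	16	89383725	89317317	C	T	forward	T	SNP	0.45	skin	FALSE
rs1800414	15	28197037	27951891	T	C	forward	C	SNP	0.06	skin	FALSE
rs10756819	9	16858084	16858084	G	A	forward	A	SNP	0.41	skin	FALSE
rs2238289	15	28453215	28208069	A	G	forward	G	SNP	0.21	skin	FALSE
rs17128291	15	48389924	48097727	A	G	forward	G	SNP	0.08	skin	FALSE
rs6497292	15	28496195	28251049	A	G	forward	G	SNP	0.16	skin	FALSE
rs1129038	15	28356859	28111713	C	T	reverse	G	SNP	0.26	skin	FALSE
rs1667394	15	28530182	28285036	T	C	reverse	G	SNP	0.21	skin	FALSE
rs1126809	11	89017961	89284793	G	A	forward	A	SNP	0.15	skin	FALSE
rs1470608	15	28288121	28042975	G	T	reverse	A	SNP	0.21	skin	FALSE
rs1426654	15	48426484	48134287	A	G	forward	G	SNP	0.35	skin	FALSE
rs6119471	20	32785212	34197408	G	C	forward	C	SNP	0.12	skin	FALSE
rs1545397	15	28187772	27942626	A	T	forward	T	SNP	0.24	skin	FALSE
rs6059655	20	32665748	34077944	G	A	reverse	T	SNP	0.09	skin	FALSE
rs12441727	15	27951891	27706745	G	A	forward	A	SNP	0.11	skin	FALSE
rs3212355	16	89984378	89917970	C	T	forward	T	SNP	0.29	skin	FALSE
rs8051733	16	90024206	89957798	A	G	reverse	C	SNP	0.24	skin	FALSE
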