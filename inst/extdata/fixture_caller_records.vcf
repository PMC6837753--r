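##fileformat=VCFv4.2
##INFO=<ID=Caller,Number=1,Type=String,Description="Variant caller">
##INFO=<ID=AF1KG,Number=1,Type=Float,Description="1000 genomes allele frequency">
##INFO=<ID=AFEXAC,Number=1,Type=Float,Description="ExAC allele frequency">
##INFO=<ID=COSMIC,Number=0,Type=Flag,Description="Reported in COSMIC">
##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">
##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	NORMAL	TUMOR
chr1	100	.	A	T	.	PASS	Caller=Mutect2	AD:DP	30,0:30	40,20:60
chr1	200	.	C	G	.	panel_of_normals	Caller=Mutect2	AD:DP	30,0:30	40,20:60
chr1	300	.	G	A	.	artifact	Caller=Mutect2	AD:DP	30,0:30	40,20:60
chr1	400	.	T	C	.	PASS	Caller=VarScan2	AD:DP	30,0:30	40,20:60
chr1	500	.	A	G	.	germline	Caller=VarScan2	AD:DP	30,0:30	40,20:60
chr1	600	.	C	T	.	PASS	Caller=SomaticSniper	AD:DP	30,0:30	40,20:60
chr1	700	.	G	C	.	LowQual	Caller=SomaticSniper	AD:DP	30,0:30	40,20:60
chr1	800	.	T	A	.	Tier1	Caller=MuSe	AD:DP	30,0:30	40,20:60
chr1	900	.	A	C	.	Tier3	Caller=MuSe	AD:DP	30,0:30	40,20:60
chr1	1000	.	C	A	.	Tier5	Caller=MuSe	AD:DP	30,0:30	40,20:60
chr1	1100	.	G	T	.	Tier6	Caller=MuSe	AD:DP	30,0:30	40,20:60
chr1	1200	.	T	G	.	PASS	Caller=Mutect2;AF1KG=0.02	AD:DP	30,0:30	40,20:60
chr1	1300	.	A	T	.	PASS	Caller=Mutect2;AF1KG=0.02;COSMIC	AD:DP	30,0:30	40,20:60
chr1	1400	.	C	G	.	PASS	Caller=Mutect2;AFEXAC=0.5	AD:DP	30,0:30	40,20:60
chr1	1500	.	G	A	.	PASS	Caller=Mutect2;AF1KG=0.005;AFEXAC=0.008	AD:DP	30,0:30	98,2:100
chr1	1600	.	T	C	.	PASS	Caller=Mutect2	AD:DP	10,0:10	5,3:8
chr1	1700	.	A	G	.	PASS	Caller=Mutect2	AD:DP	5,0:5	50,50:100
chr1	1800	.	C	T	.	PASS	Caller=Mutect2	AD:DP	198,2:200	10,10:20
chr1	1900	.	G	GA	.	PASS	Caller=Mutect2	AD:DP	30,0:30	40,20:60
chr1	2000	.	TA	T	.	PASS	Caller=VarScan2	AD:DP	30,0:30	40,20:60
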