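type_id	allele_name	class	precedence	pos	end	ref	alt	aa_detail	res100	res340	indel_kind
1	GR	combo	3	NA	NA	NA	NA	Gly100/Arg340	G	R	NA
2	EQ	combo	3	NA	NA	NA	NA	Glu100/Gln340	E	Q	NA
3	Jikkoku	point_snp	2	38382746	NA	G	T	Gly94Val	NA	NA	NA
4	Calrose76	point_snp	2	38383363	NA	C	T	Leu266Phe	NA	NA	NA
5	Reimei	point_snp	2	38385083	NA	G	C	Asp349His	NA	NA	NA
6	new_allele	long_deletion	1	38381879	38383157	NA	NA	1279-bp deletion	NA	NA	NA
7	DGWG	long_deletion	1	38382762	38383144	NA	NA	383-bp deletion	NA	NA	NA
8	9311	point_snp	2	38385064	NA	C	A	Tyr342*	NA	NA	NA
9	Aijiao-Nante	indel	2	38382846	38382847	NA	NA	Arg130fs	NA	NA	deletion
10	Zhayeqing8	point_snp	2	38383286	NA	C	T	Pro240Leu	NA	NA	NA
11	ER	combo	3	NA	NA	NA	NA	Glu100/Arg340	E	R	NA
12	bm	point_snp	2	38384938	NA	C	A	Tyr300*	NA	NA	NA
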