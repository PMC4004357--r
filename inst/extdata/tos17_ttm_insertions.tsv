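detected_by	line	chrom	tail_pos	head_pos	tail_pos2	head_pos2	tsd_size	tsd_tail	tsd_head	direction	confirmed
TIF;RelocaTE	ttm2	chr04	30259052	30259056			5	GTTTC	GTTTC	Forward	Yes
TIF;RelocaTE	ttm2	chr05	1925905	1925909			5	CTATC	CTATC	Forward	Yes
TIF;RelocaTE	ttm2	chr10	22134718	22134714			5	CTTGC	CTTGC	Reverse	Yes
TIF;RelocaTE	ttm2	chr10	22531003	22531007			5	ACTTT	ACTTT	Forward	Yes
TIF	ttm5	chr01	34453645	34453641			5	CTTTG	CTTTG	Reverse	Yes
TIF;RelocaTE	ttm5	chr02	1004769	1004765			5	ATACC	ATACC	Reverse	Yes
TIF;RelocaTE	ttm5	chr02	31596628	31596632			5	CTAAT	CTAAT	Forward	Yes
TIF;RelocaTE	ttm5	chr03	741226	741222			5	GCTGC	GCTGC	Reverse	Yes
TIF;RelocaTE	ttm5	chr03	8304678	8304674			5	GAATA	GAATA	Reverse	Yes
TIF	ttm5	chr06	24967881	24967877			5	TGCAT	TGCAT	Reverse	Yes
TIF	ttm5	chr07	20064391	20064395	20080552	20080556	5	CTTAT	CTTAT	Forward	Yes
TIF;RelocaTE	ttm5	chr09	12970618	12970614			5	CATGC	CATGC	Reverse	Yes
RelocaTE	ttm5	chr10	14739090	14739094			5		GAACT	Forward	No
TIF	ttm5	chr10	19069885	19069889			5	ACTTG	ACTTG	Forward	Yes
TIF;RelocaTE	ttm5	chr10	21583054	21583058			5	CTTAT	CTTAT	Forward	Yes
TIF;RelocaTE	ttm5	chr12	2155899	2155895			5	GGAAC	GGAAC	Reverse	Yes
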