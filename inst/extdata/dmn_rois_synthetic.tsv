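label	region	hemisphere	x	y	z
MFC.L	MFC	left	-8	52	6
MFC.R	MFC	right	8	52	6
PCC.L	PCC	left	-6	-50	30
PCC.R	PCC	right	6	-50	30
PCu.L	PCu	left	-8	-62	40
PCu.R	PCu	right	8	-62	40
LTL.L	LTL	left	-58	-24	-8
LTL.R	LTL	right	58	-24	-8
MTL.L	MTL	left	-28	-20	-20
MTL.R	MTL	right	28	-20	-20
IPL.L	IPL	left	-46	-60	35
IPL.R	IPL	right	46	-60	35
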