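label	region	hemisphere	subsystem	x	y	z
L-AICb	AICb	L	cerebellar	-22	-45	-49
R-AICb	AICb	R	cerebellar	16	-45	-49
L-BG	BG	L	subcortical	-25	-14	8
R-BG	BG	R	subcortical	22	-2	12
L-DN	DN	L	cerebellar	-28	-55	-43
R-DN	DN	R	cerebellar	19	-55	-39
L-SMA	SMA	L	cortical	-5	-4	57
R-SMA	SMA	R	cortical	5	-4	57
L-SPL	SPL	L	cortical	-22	-62	54
R-SPL	SPL	R	cortical	16	-66	57
L-M1	M1	L	cortical	-38	-22	56
R-M1	M1	R	cortical	38	-22	56
L-PMd	PMd	L	cortical	-22	-13	57
R-PMd	PMd	R	cortical	28	-10	54
L-PMv	PMv	L	cortical	-49	-1	38
R-PMv	PMv	R	cortical	53	0	25
L-SCb	SCb	L	cerebellar	-25	-56	-21
R-SCb	SCb	R	cerebellar	16	-59	-21
L-Th	Th	L	subcortical	-10	-20	11
R-Th	Th	R	subcortical	7	-20	11
R-PCG	PCG	R	cortical	37	-34	53
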