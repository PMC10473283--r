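label	x	y	z
L1	-12.2422699814293	27.6787049891574	50.2183509113456
L2	-47.6062773916225	59.8532639001014	-11.6081681340251
L3	-29.2581452339926	-40.3440377998373	-38.3288158301184
R1	12.2422699814293	27.6787049891574	50.2183509113456
R2	47.6062773916225	59.8532639001014	-11.6081681340251
R3	29.2581452339926	-40.3440377998373	-38.3288158301184
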