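SYN_SET_01	synthetic gene set SYN_SET_01	g000065	g000153	g000074	g000146	g000122	g000049	g000128	g000047	g000024	g000071
SYN_SET_02	synthetic gene set SYN_SET_02	g000089	g000165	g000110	g000020	g000154	g000114	g000111	g000131	g000041	g000200	g000027	g000164	g000109
SYN_SET_03	synthetic gene set SYN_SET_03	g000162	g000092	g000104	g000003	g000058	g000042	g000024	g000158	g000043	g000143	g000150	g000196	g000136	g000036
SYN_SET_04	synthetic gene set SYN_SET_04	g000146	g000109	g000092	g000197	g000004	g000178	g000099	g000177	g000154	g000114	g000006	g000134	g000130
SYN_SET_05	synthetic gene set SYN_SET_05	g000003	g000118	g000149	g000002	g000102	g000186	g000138	g000040	g000005	g000033	g000177	g000103	g000109
SYN_SET_06	synthetic gene set SYN_SET_06	g000073	g000157	g000076	g000009	g000035	g000016	g000101	g000069	g000118	g000130	g000082	g000152	g000113	g000146	g000193	g000110	g000104	g000183	g000040
SYN_SET_07	synthetic gene set SYN_SET_07	g000057	g000100	g000042	g000146	g000091	g000013	g000181	g000054	g000083	g000032	g000060	g000029	g000081	g000108
SYN_SET_08	synthetic gene set SYN_SET_08	g000121	g000085	g000126	g000171	g000186	g000112	g000072	g000029	g000183	g000166	g000001	g000141	g000133	g000055	g000144	g000043	g000042	g000184
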