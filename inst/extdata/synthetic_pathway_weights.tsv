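gene	NFkB	Wnt	TGFb
G0001	2.144	0	0
G0002	0.402	0	0
G0003	0.653	0	0
G0004	0.794	0	0
G0005	0.515	0	0
G0006	0.526	0	0
G0007	1.374	0	0
G0008	0.942	0	0
G0009	1.076	0	0
G0010	2.095	0	0
G0011	1.178	0	0
G0012	2.358	0	0
G0013	2.141	0	0
G0014	1.162	0	0
G0015	1.948	0	0
G0016	1.234	0	0
G0017	0.553	0	0
G0018	0.846	0	0
G0019	0.998	0	0
G0020	1.494	0	0
G0021	1.42	0	0
G0022	1.353	0	0
G0023	1.653	0	0
G0024	0.306	0	0
G0025	1.636	0	0
G0026	1.092	0	0
G0027	1.376	0	0
G0028	1.296	0	0
G0029	0.508	0	0
G0030	0.862	0	0
G0031	0	-1.235	0
G0032	0	-0.441	0
G0033	0	-0.745	0
G0034	0	-0.839	0
G0035	0	-1.01	0
G0036	0	-1.081	0
G0037	0	-0.301	0
G0038	0	-1.353	0
G0039	0	-0.871	0
G0040	0	-0.643	0
G0041	0	-0.191	0
G0042	0	-1.15	0
G0043	0	-0.943	0
G0044	0	-1.456	0
G0045	0	-0.996	0
G0046	0	-1.001	0
G0047	0	-0.125	0
G0048	0	-0.504	0
G0049	0	-0.75	0
G0050	0	-0.334	0
G0051	0	-0.931	0
G0052	0	-0.804	0
G0053	0	-0.616	0
G0054	0	0.054	0
G0055	0	-0.438	0
G0056	0	-0.559	0
G0057	0	-1.584	0
G0058	0	-0.641	0
G0059	0	-0.717	0
G0060	0	-1.25	0
G0061	0	0	0.553
G0062	0	0	0.611
G0063	0	0	0.881
G0064	0	0	0.993
G0065	0	0	0.723
G0066	0	0	1.276
G0067	0	0	1.038
G0068	0	0	1.307
G0069	0	0	1.382
G0070	0	0	0.99
G0071	0	0	0.803
G0072	0	0	-0.146
G0073	0	0	0.069
G0074	0	0	-0.107
G0075	0	0	-0.648
G0076	0	0	-0.428
G0077	0	0	-0.122
G0078	0	0	0.11
G0079	0	0	0.456
G0080	0	0	2.196
G0081	0	0	0.74
G0082	0	0	0.503
G0083	0	0	0.52
G0084	0	0	0.225
G0085	0	0	-0.055
G0086	0	0	0.282
G0087	0	0	0.258
G0088	0	0	0.287
G0089	0	0	-0.75
G0090	0	0	0.911
G0091	0	0	0
G0092	0	0	0
G0093	0	0	0
G0094	0	0	0
G0095	0	0	0
G0096	0	0	0
G0097	0	0	0
G0098	0	0	0
G0099	0	0	0
G0100	0	0	0
G0101	0	0	0
G0102	0	0	0
G0103	0	0	0
G0104	0	0	0
G0105	0	0	0
G0106	0	0	0
G0107	0	0	0
G0108	0	0	0
G0109	0	0	0
G0110	0	0	0
G0111	0	0	0
G0112	0	0	0
G0113	0	0	0
G0114	0	0	0
G0115	0	0	0
G0116	0	0	0
G0117	0	0	0
G0118	0	0	0
G0119	0	0	0
G0120	0	0	0
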