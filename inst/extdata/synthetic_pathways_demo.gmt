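SYNTHETIC_PATHWAY_CELL_CYCLE	synthetic demo gene set	GENE0001	GENE0002	GENE0003	GENE0004	GENE0005	GENE0006	GENE0007	GENE0008	GENE0009	GENE0010	GENE0011	GENE0012	GENE0013	GENE0014	GENE0015
SYNTHETIC_PATHWAY_APOPTOSIS	synthetic demo gene set	GENE0010	GENE0011	GENE0012	GENE0013	GENE0014	GENE0015	GENE0016	GENE0017	GENE0018	GENE0019	GENE0020	GENE0021	GENE0022	GENE0023	GENE0024	GENE0025
SYNTHETIC_PATHWAY_ERBB_SIGNALING	synthetic demo gene set	GENE0026	GENE0027	GENE0028	GENE0029	GENE0030	GENE0031	GENE0032	GENE0033	GENE0034	GENE0035	GENE0036	GENE0037	GENE0038	GENE0039	GENE0040
SYNTHETIC_PATHWAY_PI3K_AKT	synthetic demo gene set	GENE0035	GENE0036	GENE0037	GENE0038	GENE0039	GENE0040	GENE0041	GENE0042	GENE0043	GENE0044	GENE0045	GENE0046	GENE0047	GENE0048	GENE0049	GENE0050	GENE0051	GENE0052	GENE0053	GENE0054	GENE0055
SYNTHETIC_PATHWAY_MAPK	synthetic demo gene set	GENE0050	GENE0051	GENE0052	GENE0053	GENE0054	GENE0055	GENE0056	GENE0057	GENE0058	GENE0059	GENE0060	GENE0061	GENE0062	GENE0063	GENE0064	GENE0065	GENE0066	GENE0067	GENE0068	GENE0069	GENE0070
SYNTHETIC_PATHWAY_ADHESION	synthetic demo gene set	GENE0065	GENE0066	GENE0067	GENE0068	GENE0069	GENE0070	GENE0071	GENE0072	GENE0073	GENE0074	GENE0075	GENE0076	GENE0077	GENE0078	GENE0079	GENE0080	GENE0081	GENE0082	GENE0083	GENE0084	GENE0085
SYNTHETIC_PATHWAY_METABOLISM	synthetic demo gene set	GENE0080	GENE0081	GENE0082	GENE0083	GENE0084	GENE0085	GENE0086	GENE0087	GENE0088	GENE0089	GENE0090	GENE0091	GENE0092	GENE0093	GENE0094	GENE0095	GENE0096	GENE0097	GENE0098	GENE0099	GENE0100
SYNTHETIC_PATHWAY_IMMUNE	synthetic demo gene set	GENE0005	GENE0020	GENE0045	GENE0060	GENE0075	GENE0090	GENE0095
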