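mirna	gene	tier
hsa-miR-sim-001	GENE0049	high_prediction
hsa-miR-sim-001	GENE0065	high_prediction
hsa-miR-sim-001	GENE0025	experimentally_observed
hsa-miR-sim-001	GENE0074	experimentally_observed
hsa-miR-sim-001	GENE0018	experimentally_observed
hsa-miR-sim-001	GENE0100	experimentally_observed
hsa-miR-sim-001	GENE0047	experimentally_observed
hsa-miR-sim-001	GENE0024	high_prediction
hsa-miR-sim-001	GENE0071	experimentally_observed
hsa-miR-sim-001	GENE0089	experimentally_observed
hsa-miR-sim-001	GENE0037	experimentally_observed
hsa-miR-sim-001	GENE0020	experimentally_observed
hsa-miR-sim-002	GENE0084	high_prediction
hsa-miR-sim-002	GENE0034	high_prediction
hsa-miR-sim-002	GENE0092	high_prediction
hsa-miR-sim-002	GENE0003	high_prediction
hsa-miR-sim-002	GENE0058	high_prediction
hsa-miR-sim-002	GENE0042	experimentally_observed
hsa-miR-sim-002	GENE0024	high_prediction
hsa-miR-sim-002	GENE0030	experimentally_observed
hsa-miR-sim-002	GENE0043	high_prediction
hsa-miR-sim-002	GENE0015	high_prediction
hsa-miR-sim-002	GENE0022	high_prediction
hsa-miR-sim-002	GENE0096	high_prediction
hsa-miR-sim-003	GENE0099	high_prediction
hsa-miR-sim-003	GENE0088	high_prediction
hsa-miR-sim-003	GENE0087	experimentally_observed
hsa-miR-sim-003	GENE0049	experimentally_observed
hsa-miR-sim-003	GENE0026	experimentally_observed
hsa-miR-sim-003	GENE0006	experimentally_observed
hsa-miR-sim-003	GENE0095	high_prediction
hsa-miR-sim-003	GENE0002	experimentally_observed
hsa-miR-sim-003	GENE0003	high_prediction
hsa-miR-sim-003	GENE0021	experimentally_observed
hsa-miR-sim-003	GENE0093	experimentally_observed
hsa-miR-sim-003	GENE0058	high_prediction
hsa-miR-sim-004	GENE0084	experimentally_observed
hsa-miR-sim-004	GENE0009	high_prediction
hsa-miR-sim-004	GENE0035	high_prediction
hsa-miR-sim-004	GENE0093	experimentally_observed
hsa-miR-sim-004	GENE0016	high_prediction
hsa-miR-sim-004	GENE0092	experimentally_observed
hsa-miR-sim-004	GENE0069	high_prediction
hsa-miR-sim-004	GENE0095	experimentally_observed
hsa-miR-sim-004	GENE0002	high_prediction
hsa-miR-sim-004	GENE0082	experimentally_observed
hsa-miR-sim-004	GENE0024	high_prediction
hsa-miR-sim-004	GENE0018	high_prediction
hsa-miR-sim-005	GENE0091	high_prediction
hsa-miR-sim-005	GENE0013	experimentally_observed
hsa-miR-sim-005	GENE0053	experimentally_observed
hsa-miR-sim-005	GENE0054	high_prediction
hsa-miR-sim-005	GENE0083	high_prediction
hsa-miR-sim-005	GENE0032	high_prediction
hsa-miR-sim-005	GENE0080	experimentally_observed
hsa-miR-sim-005	GENE0060	experimentally_observed
hsa-miR-sim-005	GENE0029	high_prediction
hsa-miR-sim-005	GENE0081	experimentally_observed
hsa-miR-sim-005	GENE0073	experimentally_observed
hsa-miR-sim-005	GENE0085	high_prediction
hsa-miR-sim-006	GENE0005	high_prediction
hsa-miR-sim-006	GENE0073	experimentally_observed
hsa-miR-sim-006	GENE0055	high_prediction
hsa-miR-sim-006	GENE0016	high_prediction
hsa-miR-sim-006	GENE0090	experimentally_observed
hsa-miR-sim-006	GENE0043	high_prediction
hsa-miR-sim-006	GENE0042	high_prediction
hsa-miR-sim-006	GENE0094	experimentally_observed
hsa-miR-sim-006	GENE0057	experimentally_observed
hsa-miR-sim-006	GENE0029	high_prediction
hsa-miR-sim-006	GENE0025	experimentally_observed
hsa-miR-sim-006	GENE0063	high_prediction
hsa-miR-sim-007	GENE0031	experimentally_observed
hsa-miR-sim-007	GENE0034	high_prediction
hsa-miR-sim-007	GENE0094	high_prediction
hsa-miR-sim-007	GENE0096	high_prediction
hsa-miR-sim-007	GENE0006	high_prediction
hsa-miR-sim-007	GENE0086	high_prediction
hsa-miR-sim-007	GENE0038	experimentally_observed
hsa-miR-sim-007	GENE0097	experimentally_observed
hsa-miR-sim-007	GENE0084	high_prediction
hsa-miR-sim-007	GENE0015	high_prediction
hsa-miR-sim-007	GENE0099	high_prediction
hsa-miR-sim-007	GENE0042	high_prediction
hsa-miR-sim-008	GENE0025	high_prediction
hsa-miR-sim-008	GENE0092	experimentally_observed
hsa-miR-sim-008	GENE0061	high_prediction
hsa-miR-sim-008	GENE0062	experimentally_observed
hsa-miR-sim-008	GENE0014	experimentally_observed
hsa-miR-sim-008	GENE0034	experimentally_observed
hsa-miR-sim-008	GENE0066	experimentally_observed
hsa-miR-sim-008	GENE0032	high_prediction
hsa-miR-sim-008	GENE0027	high_prediction
hsa-miR-sim-008	GENE0010	high_prediction
hsa-miR-sim-008	GENE0057	high_prediction
hsa-miR-sim-008	GENE0028	experimentally_observed
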