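IMMUNE_MARKERS	synthetic placeholder immune signature (141 genes)	IMM001	IMM002	IMM003	IMM004	IMM005	IMM006	IMM007	IMM008	IMM009	IMM010	IMM011	IMM012	IMM013	IMM014	IMM015	IMM016	IMM017	IMM018	IMM019	IMM020	IMM021	IMM022	IMM023	IMM024	IMM025	IMM026	IMM027	IMM028	IMM029	IMM030	IMM031	IMM032	IMM033	IMM034	IMM035	IMM036	IMM037	IMM038	IMM039	IMM040	IMM041	IMM042	IMM043	IMM044	IMM045	IMM046	IMM047	IMM048	IMM049	IMM050	IMM051	IMM052	IMM053	IMM054	IMM055	IMM056	IMM057	IMM058	IMM059	IMM060	IMM061	IMM062	IMM063	IMM064	IMM065	IMM066	IMM067	IMM068	IMM069	IMM070	IMM071	IMM072	IMM073	IMM074	IMM075	IMM076	IMM077	IMM078	IMM079	IMM080	IMM081	IMM082	IMM083	IMM084	IMM085	IMM086	IMM087	IMM088	IMM089	IMM090	IMM091	IMM092	IMM093	IMM094	IMM095	IMM096	IMM097	IMM098	IMM099	IMM100	IMM101	IMM102	IMM103	IMM104	IMM105	IMM106	IMM107	IMM108	IMM109	IMM110	IMM111	IMM112	IMM113	IMM114	IMM115	IMM116	IMM117	IMM118	IMM119	IMM120	IMM121	IMM122	IMM123	IMM124	IMM125	IMM126	IMM127	IMM128	IMM129	IMM130	IMM131	IMM132	IMM133	IMM134	IMM135	IMM136	IMM137	IMM138	IMM139	IMM140	IMM141
STROMAL_MARKERS	synthetic placeholder stromal signature (141 genes)	STR001	STR002	STR003	STR004	STR005	STR006	STR007	STR008	STR009	STR010	STR011	STR012	STR013	STR014	STR015	STR016	STR017	STR018	STR019	STR020	STR021	STR022	STR023	STR024	STR025	STR026	STR027	STR028	STR029	STR030	STR031	STR032	STR033	STR034	STR035	STR036	STR037	STR038	STR039	STR040	STR041	STR042	STR043	STR044	STR045	STR046	STR047	STR048	STR049	STR050	STR051	STR052	STR053	STR054	STR055	STR056	STR057	STR058	STR059	STR060	STR061	STR062	STR063	STR064	STR065	STR066	STR067	STR068	STR069	STR070	STR071	STR072	STR073	STR074	STR075	STR076	STR077	STR078	STR079	STR080	STR081	STR082	STR083	STR084	STR085	STR086	STR087	STR088	STR089	STR090	STR091	STR092	STR093	STR094	STR095	STR096	STR097	STR098	STR099	STR100	STR101	STR102	STR103	STR104	STR105	STR106	STR107	STR108	STR109	STR110	STR111	STR112	STR113	STR114	STR115	STR116	STR117	STR118	STR119	STR120	STR121	STR122	STR123	STR124	STR125	STR126	STR127	STR128	STR129	STR130	STR131	STR132	STR133	STR134	STR135	STR136	STR137	STR138	STR139	STR140	STR141
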