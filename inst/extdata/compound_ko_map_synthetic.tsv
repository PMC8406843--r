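compound_id	ko_id	class
C00022	K90003	SCFA
C00022	K90008	SCFA
C00022	K90017	SCFA
C00022	K90021	SCFA
C00022	K90022	SCFA
C00022	K90039	SCFA
C00022	K90049	SCFA
C00022	K90056	SCFA
C00022	K90064	SCFA
C00022	K90085	SCFA
C00022	K90106	SCFA
C00022	K90107	SCFA
C00022	K90108	SCFA
C00022	K90117	SCFA
C00022	K90130	SCFA
C00022	K90135	SCFA
C00022	K90140	SCFA
C00022	K90143	SCFA
C00024	K90002	SCFA
C00024	K90027	SCFA
C00024	K90029	SCFA
C00024	K90041	SCFA
C00024	K90045	SCFA
C00024	K90052	SCFA
C00024	K90053	SCFA
C00024	K90058	SCFA
C00024	K90067	SCFA
C00024	K90077	SCFA
C00024	K90079	SCFA
C00024	K90082	SCFA
C00024	K90085	SCFA
C00024	K90087	SCFA
C00024	K90094	SCFA
C00024	K90101	SCFA
C00024	K90104	SCFA
C00024	K90114	SCFA
C00024	K90120	SCFA
C00024	K90133	SCFA
C00024	K90147	SCFA
C00024	K90148	SCFA
C00033	K90010	SCFA
C00033	K90023	SCFA
C00033	K90032	SCFA
C00033	K90042	SCFA
C00033	K90043	SCFA
C00033	K90047	SCFA
C00033	K90058	SCFA
C00033	K90063	SCFA
C00033	K90066	SCFA
C00033	K90071	SCFA
C00033	K90072	SCFA
C00033	K90073	SCFA
C00033	K90074	SCFA
C00033	K90085	SCFA
C00033	K90091	SCFA
C00033	K90099	SCFA
C00033	K90102	SCFA
C00033	K90123	SCFA
C00033	K90125	SCFA
C00033	K90129	SCFA
C00042	K90004	SCFA
C00042	K90029	SCFA
C00042	K90040	SCFA
C00042	K90047	SCFA
C00042	K90069	SCFA
C00042	K90081	SCFA
C00042	K90082	SCFA
C00042	K90087	SCFA
C00042	K90098	SCFA
C00042	K90101	SCFA
C00042	K90115	SCFA
C00042	K90128	SCFA
C00042	K90139	SCFA
C00042	K90141	SCFA
C00136	K90004	SCFA
C00136	K90005	SCFA
C00136	K90018	SCFA
C00136	K90021	SCFA
C00136	K90041	SCFA
C00136	K90045	SCFA
C00136	K90056	SCFA
C00136	K90074	SCFA
C00136	K90121	SCFA
C00136	K90127	SCFA
C00163	K90004	SCFA
C00163	K90019	SCFA
C00163	K90030	SCFA
C00163	K90034	SCFA
C00163	K90050	SCFA
C00163	K90051	SCFA
C00163	K90054	SCFA
C00163	K90070	SCFA
C00163	K90077	SCFA
C00163	K90088	SCFA
C00163	K90101	SCFA
C00163	K90111	SCFA
C00163	K90139	SCFA
C00163	K90144	SCFA
C00186	K90002	SCFA
C00186	K90013	SCFA
C00186	K90017	SCFA
C00186	K90018	SCFA
C00186	K90031	SCFA
C00186	K90050	SCFA
C00186	K90061	SCFA
C00186	K90063	SCFA
C00186	K90068	SCFA
C00186	K90099	SCFA
C00186	K90124	SCFA
C00186	K90145	SCFA
C00246	K90021	SCFA
C00246	K90027	SCFA
C00246	K90031	SCFA
C00246	K90035	SCFA
C00246	K90039	SCFA
C00246	K90041	SCFA
C00246	K90064	SCFA
C00246	K90081	SCFA
C00246	K90083	SCFA
C00246	K90085	SCFA
C00246	K90101	SCFA
C00246	K90111	SCFA
C00246	K90119	SCFA
C00246	K90121	SCFA
C00246	K90124	SCFA
C00246	K90128	SCFA
C00803	K90052	BCFA
C00803	K90087	BCFA
C00803	K90092	BCFA
C00803	K90115	BCFA
C00803	K90125	BCFA
C02632	K90008	BCFA
C02632	K90015	BCFA
C02632	K90027	BCFA
C02632	K90069	BCFA
C02632	K90129	BCFA
C02632	K90147	BCFA
C08262	K90092	BCFA
C08262	K90106	BCFA
C08262	K90111	BCFA
C08262	K90134	BCFA
C08262	K90148	BCFA
C18319	K90031	BCFA
C18319	K90075	BCFA
C18319	K90084	BCFA
C18319	K90117	BCFA
C18319	K90140	BCFA
C21399	K90069	BCFA
C21399	K90095	BCFA
C21399	K90097	BCFA
C21399	K90126	BCFA
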