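VASCULAR_SMOOTH_MUSCLE_CONTRACTION	toy pathway	g173	g197	g057	g037	g029	g182
FOCAL_ADHESION	toy pathway	g086	g120	g054	g148	g095	g016	g057	g108	g089	g113	g119	g177
DILATED_CARDIOMYOPATHY	toy pathway	g171	g054	g128	g087	g134	g131	g018
CARDIAC_MUSCLE_CONTRACTION	toy pathway	g147	g197	g081	g137	g132	g107	g180	g200	g136	g040	g049	g060	g035	g080	g105
CELL_CYCLE	toy pathway	g056	g083	g116	g154	g093	g006	g073	g161	g172	g151
TGF_BETA_SIGNALING	toy pathway	g068	g059	g015	g071	g134	g063	g082	g149	g050	g051	g039	g025	g170	g014
NOTCH_SIGNALING	toy pathway	g131	g194	g105	g180	g087	g100	g064	g145
WNT_SIGNALING	toy pathway	g043	g130	g065	g077	g186	g191	g103	g154	g009	g161	g139
MAPK_SIGNALING	toy pathway	g038	g021	g170	g186	g091	g135	g096	g051
OXIDATIVE_PHOSPHORYLATION	toy pathway	g191	g012	g047	g193	g190	g127
ECM_RECEPTOR_INTERACTION	toy pathway	g183	g115	g170	g127	g068	g124	g130	g077	g070	g151	g083	g105	g044	g173
HEDGEHOG_SIGNALING	toy pathway	g176	g054	g139	g026	g097	g053	g121	g172	g159	g177	g045	g131	g167	g077
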