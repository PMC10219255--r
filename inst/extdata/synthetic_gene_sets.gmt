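synthetic_immune_response	synthetic fixture set	g00020	g00025	g00030	g00031	g00036	g00038	g00045	g00047	g00049	g00064	g00078	g00110	g00115	g00124	g00166	g00188	g00203	g00215	g00218	g00223	g00260	g00275	g00283	g00290	g00299
synthetic_heat_shock	synthetic fixture set	g00024	g00026	g00032	g00069	g00114	g00149	g00204	g00215	g00286	g00296	g00299	g00300
synthetic_oxphos	synthetic fixture set	g00031	g00033	g00042	g00050	g00053	g00061	g00074	g00093	g00097	g00106	g00125	g00128	g00154	g00158	g00161	g00186	g00191	g00219	g00233	g00239	g00255	g00273	g00277	g00281	g00287	g00289	g00293	g00295	g00298	g00300
synthetic_phototransduction	synthetic fixture set	g00021	g00038	g00061	g00078	g00085	g00148	g00154	g00176	g00215	g00216	g00230	g00251	g00254	g00263	g00269
synthetic_actin_cytoskeleton	synthetic fixture set	g00032	g00034	g00036	g00040	g00048	g00139	g00146	g00159	g00161	g00175	g00180	g00198	g00229	g00234	g00243	g00255	g00286	g00294	g00296	g00297
synthetic_serine_metabolism	synthetic fixture set	g00012	g00031	g00060	g00087	g00178	g00182	g00237	g00253
synthetic_mapk_cascade	synthetic fixture set	g00007	g00042	g00043	g00067	g00071	g00078	g00086	g00091	g00094	g00112	g00119	g00120	g00127	g00135	g00143	g00148	g00184	g00195	g00201	g00204	g00206	g00213	g00221	g00230	g00249	g00255	g00282
synthetic_ribosome	synthetic fixture set	g00001	g00003	g00027	g00028	g00032	g00035	g00052	g00053	g00054	g00057	g00065	g00075	g00078	g00084	g00098	g00107	g00145	g00164	g00175	g00190	g00201	g00202	g00204	g00205	g00206	g00215	g00226	g00234	g00247	g00264	g00274	g00275	g00287	g00290	g00291
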