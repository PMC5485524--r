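animal_id	sire_id	diplotype	hap_sire	hap_dam	sire_diplotype	live_weight	slaughtered
L0001	S01	A1-A3/A1-A3	A1-A3	A1-A3	A1-A3/B1-A3	68.728336101234049	FALSE
L0002	S01	B1-A3/B1-A3	B1-A3	B1-A3	A1-A3/B1-A3	55.214806781369525	TRUE
L0003	S01	A1-A3/B1-A3	A1-A3	B1-A3	A1-A3/B1-A3	52.864348215441801	FALSE
L0004	S01	A1-A3/A1-A3	A1-A3	A1-A3	A1-A3/B1-A3	55.199021320702656	FALSE
L0005	S01	B1-A3/B1-A3	B1-A3	B1-A3	A1-A3/B1-A3	50.806782588351275	FALSE
L0006	S01	A1-A3/B1-A3	A1-A3	B1-A3	A1-A3/B1-A3	56.641313784853999	TRUE
L0007	S01	B1-A3/B1-A3	B1-A3	B1-A3	A1-A3/B1-A3	64.378729273635855	TRUE
L0008	S01	B1-A3/B1-C3	B1-A3	B1-C3	A1-A3/B1-A3	61.004145003418543	FALSE
L0009	S01	A1-A3/A1-A3	A1-A3	A1-A3	A1-A3/B1-A3	59.323684003105463	FALSE
L0010	S01	A1-A3/B1-C3	A1-A3	B1-C3	A1-A3/B1-A3	55.997005812027957	TRUE
L0011	S01	B1-A3/B1-A3	B1-A3	B1-A3	A1-A3/B1-A3	58.92552623714333	FALSE
L0012	S01	A1-A3/B1-C3	A1-A3	B1-C3	A1-A3/B1-A3	57.755849770984852	FALSE
L0013	S01	A1-A3/B1-C3	A1-A3	B1-C3	A1-A3/B1-A3	55.151523390879518	FALSE
L0014	S01	A1-A3/B1-C3	A1-A3	B1-C3	A1-A3/B1-A3	61.688079629943012	TRUE
L0015	S01	A1-A3/A1-C3	A1-A3	A1-C3	A1-A3/B1-A3	43.746069319540439	TRUE
L0016	S02	B1-A3/B1-A3	B1-A3	B1-A3	B1-A3/B1-A3	56.60989671438881	TRUE
L0017	S02	A1-A3/B1-A3	B1-A3	A1-A3	B1-A3/B1-A3	53.625855684018063	FALSE
L0018	S02	B1-A3/B1-B3	B1-A3	B1-B3	B1-A3/B1-A3	40.565648850094064	FALSE
L0019	S02	A1-A3/B1-A3	B1-A3	A1-A3	B1-A3/B1-A3	59.562957672997115	TRUE
L0020	S02	A1-A3/B1-A3	B1-A3	A1-A3	B1-A3/B1-A3	56.499723421094345	TRUE
L0021	S02	A1-A3/B1-A3	B1-A3	A1-A3	B1-A3/B1-A3	60.147170332713408	FALSE
L0022	S02	A1-A3/B1-A3	B1-A3	A1-A3	B1-A3/B1-A3	49.216351106237553	FALSE
L0023	S02	A1-C3/B1-A3	B1-A3	A1-C3	B1-A3/B1-A3	45.036046487825487	TRUE
L0024	S02	B1-A3/B1-A3	B1-A3	B1-A3	B1-A3/B1-A3	64.690747343104164	FALSE
L0025	S02	B1-A3/B1-A3	B1-A3	B1-A3	B1-A3/B1-A3	44.264948544983923	TRUE
L0026	S02	A1-A3/B1-A3	B1-A3	A1-A3	B1-A3/B1-A3	75.070834176556019	FALSE
L0027	S02	A1-A3/B1-A3	B1-A3	A1-A3	B1-A3/B1-A3	45.558291729983651	TRUE
L0028	S02	A1-A3/B1-A3	B1-A3	A1-A3	B1-A3/B1-A3	55.00986294268521	TRUE
L0029	S02	B1-A3/B1-B3	B1-A3	B1-B3	B1-A3/B1-A3	63.391687815504383	FALSE
L0030	S02	B1-A3/B1-A3	B1-A3	B1-A3	B1-A3/B1-A3	61.72314439845853	TRUE
L0031	S03	A1-A3/B1-A3	B1-A3	A1-A3	A1-A3/B1-A3	66.494051641564369	TRUE
L0032	S03	A1-A3/B1-A3	A1-A3	B1-A3	A1-A3/B1-A3	52.033756745331132	FALSE
L0033	S03	A1-A3/B1-C3	A1-A3	B1-C3	A1-A3/B1-A3	65.006533594531362	TRUE
L0034	S03	A1-A3/B1-A3	A1-A3	B1-A3	A1-A3/B1-A3	54.032812676569115	TRUE
L0035	S03	A1-A3/B1-C3	A1-A3	B1-C3	A1-A3/B1-A3	46.807412938656917	FALSE
L0036	S03	A1-A3/B1-A3	B1-A3	A1-A3	A1-A3/B1-A3	53.614510803183897	FALSE
L0037	S03	A1-C3/B1-A3	B1-A3	A1-C3	A1-A3/B1-A3	62.076754078086879	FALSE
L0038	S03	A1-C3/B1-A3	B1-A3	A1-C3	A1-A3/B1-A3	69.573744668335721	TRUE
L0039	S03	A1-A3/B1-A3	B1-A3	A1-A3	A1-A3/B1-A3	54.908573007513127	FALSE
L0040	S03	B1-A3/B1-C3	B1-A3	B1-C3	A1-A3/B1-A3	43.368345793232187	FALSE
L0041	S03	A1-A3/B1-A3	B1-A3	A1-A3	A1-A3/B1-A3	54.397655136865573	FALSE
L0042	S03	A1-A3/B1-A3	A1-A3	B1-A3	A1-A3/B1-A3	68.590632938505408	FALSE
L0043	S03	B1-A3/B1-A3	B1-A3	B1-A3	A1-A3/B1-A3	61.963505241336009	FALSE
L0044	S03	A1-A3/B1-A3	B1-A3	A1-A3	A1-A3/B1-A3	57.737800234260625	TRUE
L0045	S03	A1-A3/B1-A3	A1-A3	B1-A3	A1-A3/B1-A3	42.043437604009171	TRUE
L0046	S04	A1-A3/A1-A3	A1-A3	A1-A3	A1-A3/A1-C3	57.205634206243985	FALSE
L0047	S04	A1-A3/A1-A3	A1-A3	A1-A3	A1-A3/A1-C3	59.472247174754102	TRUE
L0048	S04	A1-A3/B1-A3	A1-A3	B1-A3	A1-A3/A1-C3	60.078830861826177	TRUE
L0049	S04	A1-C3/B1-A3	A1-C3	B1-A3	A1-A3/A1-C3	49.937129108175114	TRUE
L0050	S04	A1-A3/B1-A3	A1-A3	B1-A3	A1-A3/A1-C3	61.724058427146375	FALSE
L0051	S04	A1-A3/A1-C3	A1-C3	A1-A3	A1-A3/A1-C3	57.107442523640394	TRUE
L0052	S04	A1-C3/B1-B3	A1-C3	B1-B3	A1-A3/A1-C3	59.886310853519731	FALSE
L0053	S04	A1-A3/A1-A3	A1-A3	A1-A3	A1-A3/A1-C3	60.936840928055901	FALSE
L0054	S04	A1-A3/A1-A3	A1-A3	A1-A3	A1-A3/A1-C3	54.838170181455268	TRUE
L0055	S04	A1-C3/B1-A3	A1-C3	B1-A3	A1-A3/A1-C3	59.475642645475546	TRUE
L0056	S04	A1-A3/B1-A3	A1-A3	B1-A3	A1-A3/A1-C3	62.938988417125842	FALSE
L0057	S04	A1-A3/B1-A3	A1-A3	B1-A3	A1-A3/A1-C3	48.020835826348709	FALSE
L0058	S04	A1-A3/A1-A3	A1-A3	A1-A3	A1-A3/A1-C3	62.403462631681734	TRUE
L0059	S04	A1-A3/B1-A3	A1-A3	B1-A3	A1-A3/A1-C3	58.393845711065069	TRUE
L0060	S04	A1-A3/A1-C3	A1-C3	A1-A3	A1-A3/A1-C3	47.329147103980546	TRUE
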