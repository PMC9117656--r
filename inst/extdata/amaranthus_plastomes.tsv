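no	species	sample	subgenus	total_bp	lsc_bp	ssc_bp	ir_bp	gc_percent	accession
1	Amaranthus retroflexus		Amaranthus	150244	83605	17937	24351	36.6	MN091971
2	Amaranthus dubius		Amaranthus	150524	83880	17940	24352	36.6	MN091972
3	Amaranthus spinosus	113	Amaranthus	150523	83879	17940	24352	36.6	MT526784
4	Amaranthus spinosus	11902	Amaranthus	150524	83880	17940	24352	36.6	MT526783
5	Amaranthus hypochondriacus		Amaranthus	150523	83878	17941	24352	36.6	MG836505
6	Amaranthus hybridus		Amaranthus	150690	84062	17948	24340	36.6	MT559305
7	Amaranthus palmeri		Acnida	150731	84010	18027	24347	36.6	MN091990
8	Amaranthus arenicola	JSTZ	Acnida	150632	83901	18039	24346	36.6	MN091969
9	Amaranthus arenicola	HBTS	Acnida	150630	83899	18039	24346	36.6	MZ152791
10	Amaranthus tuberculatus	GZW	Acnida	150679	83945	18042	24346	36.6	MT559304
11	Amaranthus tuberculatus	11994	Acnida	150695	83961	18042	24346	36.6	MN091967
12	Amaranthus tuberculatus	12194	Acnida	150696	83962	18042	24346	36.6	MN091968
13	Amaranthus blitum		Albersia	150621	83806	18057	24379	36.6	MT526777
14	Amaranthus crispus		Albersia	150567	83793	18060	24357	36.6	MT526778
15	Amaranthus standleyanus	11960	Albersia	150567	83793	18060	24357	36.6	MT526781
16	Amaranthus standleyanus	7433	Albersia	150568	83794	18060	24357	36.6	MT526782
17	Amaranthus tunetanus		Albersia	150581	83805	18062	24357	36.6	MT526780
18	Amaranthus deflexus		Albersia	150256	83489	18065	24351	36.6	MT526776
19	Amaranthus capensis		Albersia	150707	83928	18075	24352	36.6	MT526779
20	Amaranthus blitoides		Albersia	150667	83878	18089	24350	36.5	MT526786
21	Amaranthus albus		Albersia	150756	83943	18111	24351	36.5	MT526785
22	Amaranthus polygonoides		Albersia	149948	83896	18124	23964	36.5	MT472619
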