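isoform_id	TA	TB	TC	TD
G01.1	3.1442153074835533	-3.8152726782628417	NA	-1.924043736268728
G01.2	-4.300408334224706	-0.917044957628262	NA	-2.100184467992471
G02.1	3.1442153074835533	-3.8152726782628417	NA	-1.4750288124498532
G03.1	3.1442153074835533	-3.8152726782628417	NA	-1.924043736268728
G04.1	3.1442153074835533	-3.8152726782628417	NA	-1.924043736268728
G05.1	-4.287373951261207	3.238308024458484	NA	-1.2805504841076893
G06.1	-4.287373951261207	3.238308024458484	NA	-1.8228413036001372
G07.1	-4.287373951261207	3.238308024458484	NA	-1.8228413036001372
G08.1	-4.287373951261207	-0.27171692694228683	NA	-1.8228413036001372
G09.1	-3.9842535905423193	-2.6736298912327543	NA	-2.15053476892464
G10.1	-2.829566604399716	-3.223850169177675	NA	4.452846094813008
G11.1	-4.288623797758647	0.0060586322559815775	NA	0.45593951043214354
G12.1	-2.8692434260226793	-4.111873209217081	NA	-2.051405814921262
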