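group	marker	n_esv_total	n_esv_with_tax	n_group_esv	n_family	n_genus	n_species
metazoa	12SV5	890	245	70	69	68	14
metazoa	12Steleo	1192	1106	312	309	184	22
metazoa	12S MiFishU	13228	12935	73	69	58	14
metazoa	18SV9M	7081	6878	72	38	24	7
metazoa	COI F230	16252	15952	57	0	0	0
metazoa	COI FishE	89506	61647	498	422	166	70
metazoa	COI Leray	20190	16628	44	40	35	22
fish	12SV5	890	245	2	2	2	1
fish	12Steleo	1192	1106	110	107	49	7
fish	12S MiFishU	13228	12935	29	27	21	4
fish	18SV9M	7081	6878	9	2	0	0
fish	COI F230	16252	15952	2	0	0	0
fish	COI FishE	89506	61647	19	16	12	9
fish	COI Leray	20190	16628	0	0	0	0
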