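provenance	semi_automatic	semi_automatic_ukb
wikidata	1838	295
hpo_via_wikidata	32323	3914
hpo_via_umls	2362	423
umls_direct	1287	541
expert	0	433
prop_icd	10201	1214
prop_lexical	9660	756
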