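name	lo_cm1	hi_cm1	is_amide1
amide_AB	3000	3600	FALSE
amide_I	1585	1762	TRUE
amide_II	1473	1585	FALSE
collagen_1337	1325	1346	FALSE
carb_1160	1140	1180	FALSE
dna_rna	980	1180	FALSE
lipid_CH	2800	3000	FALSE
fp_0900	900	919.1	FALSE
fp_0919	919.1	938.2	FALSE
fp_0938	938.2	957.3	FALSE
fp_0957	957.3	976.4	FALSE
fp_0976	976.4	995.5	FALSE
fp_0996	995.5	1014.6	FALSE
fp_1015	1014.6	1033.7	FALSE
fp_1034	1033.7	1052.8	FALSE
fp_1053	1052.8	1071.9	FALSE
fp_1072	1071.9	1091	FALSE
fp_1091	1091	1110.1	FALSE
fp_1110	1110.1	1129.2	FALSE
fp_1129	1129.2	1148.3	FALSE
fp_1148	1148.3	1167.4	FALSE
fp_1167	1167.4	1186.5	FALSE
fp_1186	1186.5	1205.6	FALSE
fp_1206	1205.6	1224.7	FALSE
fp_1225	1224.7	1243.8	FALSE
fp_1244	1243.8	1262.9	FALSE
fp_1263	1262.9	1282	FALSE
fp_1282	1282	1301.1	FALSE
fp_1301	1301.1	1320.2	FALSE
fp_1320	1320.2	1339.3	FALSE
fp_1339	1339.3	1358.4	FALSE
fp_1358	1358.4	1377.5	FALSE
fp_1378	1377.5	1396.6	FALSE
fp_1397	1396.6	1415.7	FALSE
fp_1416	1415.7	1434.8000000000002	FALSE
fp_1435	1434.8000000000002	1453.9	FALSE
fp_1454	1453.9	1473	FALSE
ch_2800	2800	2840	FALSE
ch_2840	2840	2880	FALSE
ch_2880	2880	2920	FALSE
ch_2920	2920	2960	FALSE
ch_2960	2960	3000	FALSE
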