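gene_id	S0001	S0002	S0003	S0004	S0005	S0006	S0007	S0008	S0009	S0010	S0011	S0012	S0013	S0014	S0015	S0016	S0017	S0018	S0019	S0020
G0001	-1.3851	-1.5478	-0.6366	0.0535	-1.2398	-0.7636	-0.5432	1.1329	-0.6889	-0.94	-0.2292	1.0124	0.965	0.2084	-1.1636	1.1417	0.4103	0.8426	0.7084	0.8179
G0002	-0.0876	-0.0944	-1.0666	-0.4765	-0.5821	1.4837	-0.3511	0.1937	-0.5499	0.3121	1.3733	-0.7982	-0.4894	0.2949	1.3506	-0.97	0.5388	0.6119	0.9114	0.6355
G0003	0.4186	-0.2257	-0.2244	-1.4329	0.9316	1.3452	0.7576	0.5988	-1.6812	1.088	0.7582	-0.4511	-0.1665	-1.2275	-0.3651	-0.3124	0.211	1.0381	-0.3232	-0.7433
G0004	-2.3083	0.3648	0.7182	-2.3368	-1.3447	2.128	1.6287	-1.74	0.7708	0.0537	0.948	-0.5027	-1.1169	-1.867	1.098	2.7095	-1.8943	0.7759	-2.8351	2.2561
G0005	-0.9293	-1.3222	3.3678	-1.4672	-1.2267	1.9886	1.5495	-1.3955	0.2151	0.3647	-0.0462	-1.155	-1.1885	-0.0237	0.6375	3.3955	-2.646	0.0604	-3.146	1.7424
G0006	0.57	-0.5962	-0.9259	-0.4612	0.8781	-0.5399	-0.8499	-0.8264	-0.2234	-0.1328	1.0625	0.8564	1.2167	1.4127	1.3273	0.8152	0.6059	-1.7079	-0.5991	-1.502
G0007	0.105	0.0207	0.1298	1.3166	-0.1386	-1.3798	-0.2816	1.2583	1.3162	0.2517	1.304	-1.6037	0.2415	0.2708	-1.5335	0.7241	-0.1755	-0.3871	-0.6743	1.4058
G0008	1.2815	-0.4222	-0.8656	0.3755	0.2801	-0.8561	-0.6318	1.3767	-0.4754	-2.3591	2.472	0.3916	-0.4061	0.1069	-0.4798	-1.611	-0.0222	1.6019	-0.5625	-0.6045
G0009	1.891	1.4707	-0.0811	0.7207	-0.2528	1.8613	-1.2899	0.1158	1.0069	-0.385	-0.7129	-0.8343	0.1825	0.4042	0.8364	1.4191	-1.0877	-1.1124	-0.1702	-0.184
G0010	1.776	0.3625	1.7893	-0.6565	1.6214	0.0729	-0.824	-0.9341	-0.2689	0.46	-0.2819	-0.9988	0.8216	-0.3658	1.1726	-1.2055	-0.831	-0.0599	2.0709	-0.8168
G0011	2.0056	-1.4415	0.6686	-0.8233	0.4731	0.4959	0.3497	-1.5192	-0.2864	-0.3826	-0.1221	0.0398	1.4187	0.1891	0.0639	-1.1181	0.3181	-0.7419	0.4648	-0.488
G0012	1.4569	0.3526	1.8709	0.2381	0.3564	-0.7507	0.1435	0.4171	0.2474	1.2632	-0.499	1.6078	1.3196	-0.6178	1.6752	0.4604	-0.4201	0.5893	-0.4733	1.8405
G0013	-2.7874	-1.5889	2.1882	-1.3295	-1.3295	2.0415	-0.0126	-1.7704	0.1837	1.681	-1.1145	1.1125	0.8949	0.5171	1.7268	1.6363	-1.1696	-0.0546	-1.5097	1.811
G0014	0.8201	0.3801	-1.4612	0.4366	0.4271	1.3263	-0.6859	-0.3614	0.7495	-0.5231	0.0103	-0.8357	1.6034	2.5329	-0.1128	1.6601	0.7104	-0.0073	-1.0662	1.538
G0015	-0.5672	0.089	-1.4472	-0.7471	1.0802	-1.9384	0.5544	-0.089	-1.5558	1.1648	-0.4983	0.1734	0.5611	-0.8332	-1.3354	-0.644	-1.4942	2.4159	0.4191	0.2207
G0016	-0.4087	0.6401	0.1399	0.2252	1.002	0.4453	-0.0954	-0.5188	-1.3518	0.691	0.5539	0.0482	0.8087	0.2077	1.0935	-0.4979	-1.0005	0.2454	-1.2431	-0.6822
G0017	-0.3465	0.5162	-1.0728	0.5422	0.103	0.8224	0.5658	0.8385	-0.0139	0.3471	-1.0053	-1.4508	-1.4082	0.2019	1.4882	0.4254	-2.9378	-0.0606	-0.0445	0.7437
G0018	-0.3244	-1.9285	-0.3935	-1.9147	0.2766	-2.0047	0.9574	0.2151	0.3074	0.0841	-0.4434	-0.6957	0.3211	-0.546	-0.572	-0.5286	2.3727	-1.5728	-0.171	-2.9478
G0019	0.9575	0.0135	0.3288	0.7122	0.1149	-0.2332	1.0503	2.57	0.4159	0.4199	-0.0306	-0.5156	-0.7186	0.5731	1.0478	0.1751	-0.126	-1.0214	0.1809	1.3538
G0020	-1.3915	-1.2117	0.6534	0.387	-1.3046	-1.037	-1.8885	0.7894	-0.9761	0.0082	-0.8185	1.4339	-0.4695	-2.159	1.5749	-0.1859	-0.1075	0.1685	-1.5717	-0.7944
G0021	-2.9117	-0.3093	3.1171	-1.9147	-3.5467	0.6413	1.8371	-1.3515	0.3245	1.4643	-0.0371	-0.5767	1.9629	-0.2207	3.0064	4.4709	-2.6393	0.5672	-2.3144	0.9229
G0022	0.2715	-0.1298	-1.1198	-1.4687	-0.5021	-0.1237	-0.8986	-0.6303	0.6859	0.0102	0.4394	1.0783	-0.7552	-0.5468	-0.6154	-0.1381	-0.6278	0.1994	-0.0143	-0.228
G0023	0.4595	0.7496	-1.314	1.2224	-0.6509	1.2475	-0.686	-0.5623	0.1612	-0.8074	0.1613	-0.7139	-0.5374	0.1869	-0.3107	1.1252	-1.2468	-0.0074	-1.2616	-0.1
G0024	1.1097	0.6031	-0.8296	1.193	2.2503	-0.0274	-0.2835	-0.7038	-0.5762	0.4689	0.5815	1.4899	-0.1452	-2.2854	-0.5494	0.8458	0.6755	0.5038	0.2919	-0.1388
G0025	-0.4624	0.7858	-0.0087	1.1269	-1.6773	0.4294	-0.3883	-1.4707	-0.2761	-2.5351	-1.1691	-1.0344	0.2697	-0.4884	-2.3277	0.0692	1.3612	-1.3241	-1.1745	1.3133
G0026	-1.6297	0.1786	0.5881	0.3733	1.2643	-0.7743	1.2101	-0.9639	-1.5101	-1.8225	1.3797	-0.6766	1.4595	0.5887	-2.0946	0.3881	-0.1215	-0.9658	-0.2195	-0.9361
G0027	-1.0717	1.5558	-1.4631	0.017	-1.6646	-0.5886	-1.811	-0.2908	2.0383	0.0949	-0.4067	0.5814	0.8515	-0.3058	2.0356	0.7895	0.027	-0.2592	0.9456	-1.0433
G0028	0.7682	0.0624	1.2395	-0.1659	0.6684	-0.2773	0.8243	-1.0202	1.5386	2.0174	0.4841	0.4757	0.231	-0.0253	-0.6361	-0.9981	0.5081	-0.2084	-0.0018	0.6371
G0029	-3.1192	-0.6103	2.1019	-1.9877	-2.6314	0.3807	2.0413	-1.2621	2.2955	-0.3797	-0.078	1.0784	1.1474	0.2744	2.4585	0.4267	-0.771	0.3495	-2.4785	4.1135
G0030	0.7517	0.3311	0.9131	-0.4044	-0.9806	-0.1864	-0.1582	0.9661	0.5231	-0.9198	0.1709	-1.8931	1.1374	-0.642	-1.1934	0.4431	-0.3062	0.5681	-1.0547	-1.5554
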