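variety	ABD	AGS	BD	CJT	DBR	GX	JT	LTT	SNF	TG	YC
ABD	0	0.1232	0.2038	0.2377	0.1908	0.2122	0.1418	0.1647	0.2037	0.1828	0.1933
AGS	0.1232	0	0.2098	0.248	0.1889	0.2169	0.1407	0.1713	0.2007	0.1873	0.2031
BD	0.2038	0.2098	0	0.1917	0.1336	0.1504	0.2267	0.1966	0.1491	0.1448	0.145
CJT	0.2377	0.248	0.1917	0	0.1788	0.1431	0.2519	0.2188	0.1565	0.1726	0.1184
DBR	0.1908	0.1889	0.1336	0.1788	0	0.1593	0.1956	0.1636	0.122	0.122	0.1345
GX	0.2122	0.2169	0.1504	0.1431	0.1593	0	0.2349	0.1994	0.1353	0.154	0.1129
JT	0.1418	0.1407	0.2267	0.2519	0.1956	0.2349	0	0.1824	0.2087	0.1818	0.1974
LTT	0.1647	0.1713	0.1966	0.2188	0.1636	0.1994	0.1824	0	0.1625	0.1751	0.1789
SNF	0.2037	0.2007	0.1491	0.1565	0.122	0.1353	0.2087	0.1625	0	0.1371	0.1211
TG	0.1828	0.1873	0.1448	0.1726	0.122	0.154	0.1818	0.1751	0.1371	0	0.1069
YC	0.1933	0.2031	0.145	0.1184	0.1345	0.1129	0.1974	0.1789	0.1211	0.1069	0
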