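variety	n_bulks	ne	na	ho	he	nei	shi
ABD	3	1.2808	0.6038	0.1688	0.16	0.204	0.234
AGS	3	1.2771	0.6022	0.1679	0.1582	0.1971	0.2321
BD	3	1.312	0.5528	0.1767	0.1782	0.2232	0.2613
CJT	3	1.2678	0.6199	0.1546	0.1524	0.1905	0.2231
DBR	3	1.3145	0.551	0.1773	0.1794	0.2247	0.2629
GX	3	1.2959	0.5751	0.1775	0.1692	0.2114	0.2481
JT	3	1.264	0.6227	0.1657	0.1505	0.1871	0.2207
LTT	3	1.2759	0.6065	0.1591	0.1572	0.1965	0.2304
SNF	3	1.3156	0.5465	0.1824	0.1804	0.226	0.2647
TG	3	1.3237	0.5371	0.1796	0.1847	0.2315	0.2708
YC	3	1.314	0.5493	0.1842	0.1794	0.2241	0.2632
all	33	1.4402	0.0219	0.1538	0.2753	0.2916	0.4304
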