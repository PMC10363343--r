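subject,wrkmem,storym,swapped_flag
100307,0.2563,0.2006,FALSE
102816,0.2372,0.1864,FALSE
104012,0.2388,0.2045,FALSE
106521,0.2301,0.1881,FALSE
108323,0.2477,0.175,FALSE
109123,0.259,0.1862,FALSE
116726,0.2235,0.1968,FALSE
133019,0.2497,0.1992,FALSE
140117,0.2349,0.1942,FALSE
146129,0.251,0.1871,FALSE
149741,0.2653,0.1967,FALSE
151526,0.2534,0.1843,FALSE
156334,0.2549,0.1963,FALSE
158136,0.2528,0.1914,FALSE
162026,0.2557,0.1981,FALSE
166438,0.2579,0.2036,FALSE
169040,0.2604,0.1883,TRUE
175540,0.2364,0.1889,FALSE
182840,0.2549,0.187,FALSE
185442,0.238,0.1748,FALSE
191033,0.2458,0.2021,FALSE
191437,0.2373,0.1814,FALSE
192641,0.2477,0.1749,FALSE
195041,0.2562,0.1878,FALSE
200109,0.2378,0.2118,FALSE
204521,0.2449,0.1794,FALSE
205119,0.2504,0.197,FALSE
212318,0.2413,0.1867,FALSE
212823,0.2454,0.2006,FALSE
214524,0.2452,0.2049,FALSE
223929,0.2289,0.2115,FALSE
248339,0.2403,0.1728,FALSE
255639,0.246,0.1714,FALSE
257845,0.2565,0.2003,TRUE
283543,0.2675,0.201,FALSE
293748,0.2587,0.1883,FALSE
353740,0.2471,0.1941,FALSE
433839,0.2485,0.1766,FALSE
512835,0.2546,0.1846,FALSE
555348,0.2528,0.1824,FALSE
568963,0.2376,0.1933,TRUE
599671,0.2382,0.1812,FALSE
601127,0.2503,0.1965,FALSE
660951,0.2488,0.2012,FALSE
662551,0.2379,0.1976,FALSE
665254,0.2509,0.1817,FALSE
667056,0.2392,0.1856,FALSE
679770,0.2308,0.1993,FALSE
706040,0.2086,0.1677,FALSE
707749,0.2122,0.166,FALSE
715950,0.2473,0.1914,FALSE
725751,0.2648,0.1928,FALSE
735148,0.2398,0.2021,FALSE
783462,0.2479,0.1897,FALSE
814649,0.2379,0.1899,FALSE
825048,0.2393,0.1993,FALSE
872764,0.2388,0.1849,FALSE
877168,0.2377,0.1856,FALSE
891667,0.2473,0.1943,FALSE
917255,0.2564,0.2027,FALSE
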