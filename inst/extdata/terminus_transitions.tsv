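deacylate	cap_clip	pnk	alkb	five_in	three_in	five_out	three_out
0	0	0	0	P	OH	P	OH
0	0	0	0	P	P	P	P
0	0	0	0	P	cP	P	cP
0	0	0	0	P	aa	P	aa
0	0	0	0	OH	OH	OH	OH
0	0	0	0	OH	P	OH	P
0	0	0	0	OH	cP	OH	cP
0	0	0	0	OH	aa	OH	aa
0	0	0	0	cap_m7G	OH	cap_m7G	OH
0	0	0	0	cap_m7G	P	cap_m7G	P
0	0	0	0	cap_m7G	cP	cap_m7G	cP
0	0	0	0	cap_m7G	aa	cap_m7G	aa
0	0	0	0	cap_m3G	OH	cap_m3G	OH
0	0	0	0	cap_m3G	P	cap_m3G	P
0	0	0	0	cap_m3G	cP	cap_m3G	cP
0	0	0	0	cap_m3G	aa	cap_m3G	aa
0	0	0	0	ppp	OH	ppp	OH
0	0	0	0	ppp	P	ppp	P
0	0	0	0	ppp	cP	ppp	cP
0	0	0	0	ppp	aa	ppp	aa
0	0	0	1	P	OH	P	OH
0	0	0	1	P	P	P	P
0	0	0	1	P	cP	P	cP
0	0	0	1	P	aa	P	aa
0	0	0	1	OH	OH	OH	OH
0	0	0	1	OH	P	OH	P
0	0	0	1	OH	cP	OH	cP
0	0	0	1	OH	aa	OH	aa
0	0	0	1	cap_m7G	OH	cap_m7G	OH
0	0	0	1	cap_m7G	P	cap_m7G	P
0	0	0	1	cap_m7G	cP	cap_m7G	cP
0	0	0	1	cap_m7G	aa	cap_m7G	aa
0	0	0	1	cap_m3G	OH	cap_m3G	OH
0	0	0	1	cap_m3G	P	cap_m3G	P
0	0	0	1	cap_m3G	cP	cap_m3G	cP
0	0	0	1	cap_m3G	aa	cap_m3G	aa
0	0	0	1	ppp	OH	ppp	OH
0	0	0	1	ppp	P	ppp	P
0	0	0	1	ppp	cP	ppp	cP
0	0	0	1	ppp	aa	ppp	aa
0	0	1	0	P	OH	P	OH
0	0	1	0	P	P	P	OH
0	0	1	0	P	cP	P	OH
0	0	1	0	P	aa	P	aa
0	0	1	0	OH	OH	P	OH
0	0	1	0	OH	P	P	OH
0	0	1	0	OH	cP	P	OH
0	0	1	0	OH	aa	P	aa
0	0	1	0	cap_m7G	OH	cap_m7G	OH
0	0	1	0	cap_m7G	P	cap_m7G	OH
0	0	1	0	cap_m7G	cP	cap_m7G	OH
0	0	1	0	cap_m7G	aa	cap_m7G	aa
0	0	1	0	cap_m3G	OH	cap_m3G	OH
0	0	1	0	cap_m3G	P	cap_m3G	OH
0	0	1	0	cap_m3G	cP	cap_m3G	OH
0	0	1	0	cap_m3G	aa	cap_m3G	aa
0	0	1	0	ppp	OH	ppp	OH
0	0	1	0	ppp	P	ppp	OH
0	0	1	0	ppp	cP	ppp	OH
0	0	1	0	ppp	aa	ppp	aa
0	0	1	1	P	OH	P	OH
0	0	1	1	P	P	P	OH
0	0	1	1	P	cP	P	OH
0	0	1	1	P	aa	P	aa
0	0	1	1	OH	OH	P	OH
0	0	1	1	OH	P	P	OH
0	0	1	1	OH	cP	P	OH
0	0	1	1	OH	aa	P	aa
0	0	1	1	cap_m7G	OH	cap_m7G	OH
0	0	1	1	cap_m7G	P	cap_m7G	OH
0	0	1	1	cap_m7G	cP	cap_m7G	OH
0	0	1	1	cap_m7G	aa	cap_m7G	aa
0	0	1	1	cap_m3G	OH	cap_m3G	OH
0	0	1	1	cap_m3G	P	cap_m3G	OH
0	0	1	1	cap_m3G	cP	cap_m3G	OH
0	0	1	1	cap_m3G	aa	cap_m3G	aa
0	0	1	1	ppp	OH	ppp	OH
0	0	1	1	ppp	P	ppp	OH
0	0	1	1	ppp	cP	ppp	OH
0	0	1	1	ppp	aa	ppp	aa
0	1	0	0	P	OH	P	OH
0	1	0	0	P	P	P	P
0	1	0	0	P	cP	P	cP
0	1	0	0	P	aa	P	aa
0	1	0	0	OH	OH	OH	OH
0	1	0	0	OH	P	OH	P
0	1	0	0	OH	cP	OH	cP
0	1	0	0	OH	aa	OH	aa
0	1	0	0	cap_m7G	OH	P	OH
0	1	0	0	cap_m7G	P	P	P
0	1	0	0	cap_m7G	cP	P	cP
0	1	0	0	cap_m7G	aa	P	aa
0	1	0	0	cap_m3G	OH	P	OH
0	1	0	0	cap_m3G	P	P	P
0	1	0	0	cap_m3G	cP	P	cP
0	1	0	0	cap_m3G	aa	P	aa
0	1	0	0	ppp	OH	P	OH
0	1	0	0	ppp	P	P	P
0	1	0	0	ppp	cP	P	cP
0	1	0	0	ppp	aa	P	aa
0	1	0	1	P	OH	P	OH
0	1	0	1	P	P	P	P
0	1	0	1	P	cP	P	cP
0	1	0	1	P	aa	P	aa
0	1	0	1	OH	OH	OH	OH
0	1	0	1	OH	P	OH	P
0	1	0	1	OH	cP	OH	cP
0	1	0	1	OH	aa	OH	aa
0	1	0	1	cap_m7G	OH	P	OH
0	1	0	1	cap_m7G	P	P	P
0	1	0	1	cap_m7G	cP	P	cP
0	1	0	1	cap_m7G	aa	P	aa
0	1	0	1	cap_m3G	OH	P	OH
0	1	0	1	cap_m3G	P	P	P
0	1	0	1	cap_m3G	cP	P	cP
0	1	0	1	cap_m3G	aa	P	aa
0	1	0	1	ppp	OH	P	OH
0	1	0	1	ppp	P	P	P
0	1	0	1	ppp	cP	P	cP
0	1	0	1	ppp	aa	P	aa
0	1	1	0	P	OH	P	OH
0	1	1	0	P	P	P	OH
0	1	1	0	P	cP	P	OH
0	1	1	0	P	aa	P	aa
0	1	1	0	OH	OH	P	OH
0	1	1	0	OH	P	P	OH
0	1	1	0	OH	cP	P	OH
0	1	1	0	OH	aa	P	aa
0	1	1	0	cap_m7G	OH	P	OH
0	1	1	0	cap_m7G	P	P	OH
0	1	1	0	cap_m7G	cP	P	OH
0	1	1	0	cap_m7G	aa	P	aa
0	1	1	0	cap_m3G	OH	P	OH
0	1	1	0	cap_m3G	P	P	OH
0	1	1	0	cap_m3G	cP	P	OH
0	1	1	0	cap_m3G	aa	P	aa
0	1	1	0	ppp	OH	P	OH
0	1	1	0	ppp	P	P	OH
0	1	1	0	ppp	cP	P	OH
0	1	1	0	ppp	aa	P	aa
0	1	1	1	P	OH	P	OH
0	1	1	1	P	P	P	OH
0	1	1	1	P	cP	P	OH
0	1	1	1	P	aa	P	aa
0	1	1	1	OH	OH	P	OH
0	1	1	1	OH	P	P	OH
0	1	1	1	OH	cP	P	OH
0	1	1	1	OH	aa	P	aa
0	1	1	1	cap_m7G	OH	P	OH
0	1	1	1	cap_m7G	P	P	OH
0	1	1	1	cap_m7G	cP	P	OH
0	1	1	1	cap_m7G	aa	P	aa
0	1	1	1	cap_m3G	OH	P	OH
0	1	1	1	cap_m3G	P	P	OH
0	1	1	1	cap_m3G	cP	P	OH
0	1	1	1	cap_m3G	aa	P	aa
0	1	1	1	ppp	OH	P	OH
0	1	1	1	ppp	P	P	OH
0	1	1	1	ppp	cP	P	OH
0	1	1	1	ppp	aa	P	aa
1	0	0	0	P	OH	P	OH
1	0	0	0	P	P	P	P
1	0	0	0	P	cP	P	cP
1	0	0	0	P	aa	P	OH
1	0	0	0	OH	OH	OH	OH
1	0	0	0	OH	P	OH	P
1	0	0	0	OH	cP	OH	cP
1	0	0	0	OH	aa	OH	OH
1	0	0	0	cap_m7G	OH	cap_m7G	OH
1	0	0	0	cap_m7G	P	cap_m7G	P
1	0	0	0	cap_m7G	cP	cap_m7G	cP
1	0	0	0	cap_m7G	aa	cap_m7G	OH
1	0	0	0	cap_m3G	OH	cap_m3G	OH
1	0	0	0	cap_m3G	P	cap_m3G	P
1	0	0	0	cap_m3G	cP	cap_m3G	cP
1	0	0	0	cap_m3G	aa	cap_m3G	OH
1	0	0	0	ppp	OH	ppp	OH
1	0	0	0	ppp	P	ppp	P
1	0	0	0	ppp	cP	ppp	cP
1	0	0	0	ppp	aa	ppp	OH
1	0	0	1	P	OH	P	OH
1	0	0	1	P	P	P	P
1	0	0	1	P	cP	P	cP
1	0	0	1	P	aa	P	OH
1	0	0	1	OH	OH	OH	OH
1	0	0	1	OH	P	OH	P
1	0	0	1	OH	cP	OH	cP
1	0	0	1	OH	aa	OH	OH
1	0	0	1	cap_m7G	OH	cap_m7G	OH
1	0	0	1	cap_m7G	P	cap_m7G	P
1	0	0	1	cap_m7G	cP	cap_m7G	cP
1	0	0	1	cap_m7G	aa	cap_m7G	OH
1	0	0	1	cap_m3G	OH	cap_m3G	OH
1	0	0	1	cap_m3G	P	cap_m3G	P
1	0	0	1	cap_m3G	cP	cap_m3G	cP
1	0	0	1	cap_m3G	aa	cap_m3G	OH
1	0	0	1	ppp	OH	ppp	OH
1	0	0	1	ppp	P	ppp	P
1	0	0	1	ppp	cP	ppp	cP
1	0	0	1	ppp	aa	ppp	OH
1	0	1	0	P	OH	P	OH
1	0	1	0	P	P	P	OH
1	0	1	0	P	cP	P	OH
1	0	1	0	P	aa	P	OH
1	0	1	0	OH	OH	P	OH
1	0	1	0	OH	P	P	OH
1	0	1	0	OH	cP	P	OH
1	0	1	0	OH	aa	P	OH
1	0	1	0	cap_m7G	OH	cap_m7G	OH
1	0	1	0	cap_m7G	P	cap_m7G	OH
1	0	1	0	cap_m7G	cP	cap_m7G	OH
1	0	1	0	cap_m7G	aa	cap_m7G	OH
1	0	1	0	cap_m3G	OH	cap_m3G	OH
1	0	1	0	cap_m3G	P	cap_m3G	OH
1	0	1	0	cap_m3G	cP	cap_m3G	OH
1	0	1	0	cap_m3G	aa	cap_m3G	OH
1	0	1	0	ppp	OH	ppp	OH
1	0	1	0	ppp	P	ppp	OH
1	0	1	0	ppp	cP	ppp	OH
1	0	1	0	ppp	aa	ppp	OH
1	0	1	1	P	OH	P	OH
1	0	1	1	P	P	P	OH
1	0	1	1	P	cP	P	OH
1	0	1	1	P	aa	P	OH
1	0	1	1	OH	OH	P	OH
1	0	1	1	OH	P	P	OH
1	0	1	1	OH	cP	P	OH
1	0	1	1	OH	aa	P	OH
1	0	1	1	cap_m7G	OH	cap_m7G	OH
1	0	1	1	cap_m7G	P	cap_m7G	OH
1	0	1	1	cap_m7G	cP	cap_m7G	OH
1	0	1	1	cap_m7G	aa	cap_m7G	OH
1	0	1	1	cap_m3G	OH	cap_m3G	OH
1	0	1	1	cap_m3G	P	cap_m3G	OH
1	0	1	1	cap_m3G	cP	cap_m3G	OH
1	0	1	1	cap_m3G	aa	cap_m3G	OH
1	0	1	1	ppp	OH	ppp	OH
1	0	1	1	ppp	P	ppp	OH
1	0	1	1	ppp	cP	ppp	OH
1	0	1	1	ppp	aa	ppp	OH
1	1	0	0	P	OH	P	OH
1	1	0	0	P	P	P	P
1	1	0	0	P	cP	P	cP
1	1	0	0	P	aa	P	OH
1	1	0	0	OH	OH	OH	OH
1	1	0	0	OH	P	OH	P
1	1	0	0	OH	cP	OH	cP
1	1	0	0	OH	aa	OH	OH
1	1	0	0	cap_m7G	OH	P	OH
1	1	0	0	cap_m7G	P	P	P
1	1	0	0	cap_m7G	cP	P	cP
1	1	0	0	cap_m7G	aa	P	OH
1	1	0	0	cap_m3G	OH	P	OH
1	1	0	0	cap_m3G	P	P	P
1	1	0	0	cap_m3G	cP	P	cP
1	1	0	0	cap_m3G	aa	P	OH
1	1	0	0	ppp	OH	P	OH
1	1	0	0	ppp	P	P	P
1	1	0	0	ppp	cP	P	cP
1	1	0	0	ppp	aa	P	OH
1	1	0	1	P	OH	P	OH
1	1	0	1	P	P	P	P
1	1	0	1	P	cP	P	cP
1	1	0	1	P	aa	P	OH
1	1	0	1	OH	OH	OH	OH
1	1	0	1	OH	P	OH	P
1	1	0	1	OH	cP	OH	cP
1	1	0	1	OH	aa	OH	OH
1	1	0	1	cap_m7G	OH	P	OH
1	1	0	1	cap_m7G	P	P	P
1	1	0	1	cap_m7G	cP	P	cP
1	1	0	1	cap_m7G	aa	P	OH
1	1	0	1	cap_m3G	OH	P	OH
1	1	0	1	cap_m3G	P	P	P
1	1	0	1	cap_m3G	cP	P	cP
1	1	0	1	cap_m3G	aa	P	OH
1	1	0	1	ppp	OH	P	OH
1	1	0	1	ppp	P	P	P
1	1	0	1	ppp	cP	P	cP
1	1	0	1	ppp	aa	P	OH
1	1	1	0	P	OH	P	OH
1	1	1	0	P	P	P	OH
1	1	1	0	P	cP	P	OH
1	1	1	0	P	aa	P	OH
1	1	1	0	OH	OH	P	OH
1	1	1	0	OH	P	P	OH
1	1	1	0	OH	cP	P	OH
1	1	1	0	OH	aa	P	OH
1	1	1	0	cap_m7G	OH	P	OH
1	1	1	0	cap_m7G	P	P	OH
1	1	1	0	cap_m7G	cP	P	OH
1	1	1	0	cap_m7G	aa	P	OH
1	1	1	0	cap_m3G	OH	P	OH
1	1	1	0	cap_m3G	P	P	OH
1	1	1	0	cap_m3G	cP	P	OH
1	1	1	0	cap_m3G	aa	P	OH
1	1	1	0	ppp	OH	P	OH
1	1	1	0	ppp	P	P	OH
1	1	1	0	ppp	cP	P	OH
1	1	1	0	ppp	aa	P	OH
1	1	1	1	P	OH	P	OH
1	1	1	1	P	P	P	OH
1	1	1	1	P	cP	P	OH
1	1	1	1	P	aa	P	OH
1	1	1	1	OH	OH	P	OH
1	1	1	1	OH	P	P	OH
1	1	1	1	OH	cP	P	OH
1	1	1	1	OH	aa	P	OH
1	1	1	1	cap_m7G	OH	P	OH
1	1	1	1	cap_m7G	P	P	OH
1	1	1	1	cap_m7G	cP	P	OH
1	1	1	1	cap_m7G	aa	P	OH
1	1	1	1	cap_m3G	OH	P	OH
1	1	1	1	cap_m3G	P	P	OH
1	1	1	1	cap_m3G	cP	P	OH
1	1	1	1	cap_m3G	aa	P	OH
1	1	1	1	ppp	OH	P	OH
1	1	1	1	ppp	P	P	OH
1	1	1	1	ppp	cP	P	OH
1	1	1	1	ppp	aa	P	OH
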