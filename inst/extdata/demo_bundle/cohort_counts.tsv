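variant_key	gene	consequence	cases_carriers	cases_n	controls_carriers	controls_n
3:64283900:T:A	CAUSAL	missense	3	80	0	80
15:43395411:A:T	BG001	missense	0	80	1	80
2:64378480:T:G	BG002	other	5	80	5	80
18:32076964:G:T	BG003	other	9	80	3	80
3:159810271:G:A	BG004	nonsense	5	80	1	80
13:66238432:C:T	BG005	nonsense	1	80	0	80
15:78966610:T:A	BG006	other	1	80	0	80
5:113480946:C:A	BG007	nonsense	1	80	2	80
14:144370382:C:T	BG008	other	0	80	0	80
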