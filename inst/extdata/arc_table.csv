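weekday,shift_start,prevalence_pct
0,3,3.17
0,9,7.94
0,15,11.11
0,21,4.76
1,3,3.17
1,9,1.59
1,15,7.94
1,21,4.76
2,3,0.00
2,9,0.00
2,15,4.76
2,21,4.76
3,3,1.59
3,9,0.00
3,15,3.17
3,21,3.17
4,3,1.59
4,9,1.59
4,15,0.00
4,21,3.17
5,3,1.59
5,9,1.59
5,15,0.00
5,21,6.35
6,3,6.35
6,9,0.00
6,15,3.17
6,21,12.70
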