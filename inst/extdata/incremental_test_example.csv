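stage,po_watts,hr_bpm,fr_brpm
0,0,95,12.7
1,20,93,16.5
2,40,98,14.7
3,60,102,18.9
4,80,122,17.5
5,100,135,21.5
6,120,145,19.3
7,140,154,22.1
8,160,162,31
9,180,170,30
10,200,175,35.7
11,220,180,51.4
12,240,183,64.5
13,260,184,92.3
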