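chromosome	length_cM
1	266.52396039604
2	251.070531053105
3	213.963222322232
4	204.519459945995
5	199.559099909991
6	185.15497749775
7	178.763744374437
8	161.879441944194
9	159.494653465347
10	166.076669666967
11	153.675769576958
12	168.175283528353
13	125.821440144014
14	119.430207020702
15	126.298397839784
16	127.633879387939
17	130.972583258326
18	120.765688568857
19	104.835301530153
20	96.1546714671467
21	59.9058865886589
22	70.6851305130513
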