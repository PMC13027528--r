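id,age,mass_size_cm,side,grade,histology,er,pr,her2
1,63,1.8,L,2,Invasive ductal carcinoma (IDC),+,+,+
2,65,2.7,R,2,IDC,+,-,-
3,65,6.3,R,3,IDC,-,-,+
4,54,2.3,R,2,IDC,+,+,+
5,63,1.6,R,1,IDC with apocrine features,-,-,-
6,46,2.8,R,2,IDC,+,+,-
7,53,5.7,L,3,Micro-invasive carcinoma,+,-,-
8,53,6.4,R,2,IDC,-,-,+
9,53,2.6,L,2,IDC,-,-,-
10,49,1.3,R,2,Invasive breast carcinoma with papillary features,+,+,+
11,72,2.2,L,3,IDC,-,-,-
12,56,3.5,R,2,IDC,+,+,+
13,37,2.8,L,3,IDC,+,+,-
14,63,5.5,L,2,Mucinous carcinoma,+,+,-
15,37,6.1,L,3,IDC,+,+,+
16,49,6.1,R,3,IDC,+,-,+
17,46,7.3,R,2,Invasive carcinoma with extensive necrosis,-,-,-
18,50,3.0,R,2,IDC,-,-,-
19,49,5.2,R,2,IDC,+,+,-
20,53,3.3,R,3,IDC,+,-,+
21,70,6.7,L,3,Invasive lobular carcinoma (ILC),+,+,-
22,51,7.0,L,2,IDC,-,-,-
23,70,5.4,L,2,Mixed ductal and metaplastic carcinoma,-,-,-
24,45,3.2,R,3,IDC,+,+,+
25,48,4.5,R,2,IDC,+,+,+
26,67,3.6,L,3,IDC,-,-,+
27,56,2.0,R,2,IDC,-,-,-
28,48,4.5,R,3,IDC,+,+,+
29,81,2.5,L,3,ILC,+,-,+
30,82,3.7,L,3,IDC,-,-,+
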