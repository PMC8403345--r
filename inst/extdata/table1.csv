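subject,side,reader,modality,angle_deg
1,right,1,CT,14.5
1,right,1,MRI,14.9
1,right,2,CT,16.4
1,right,2,MRI,18.1
1,left,1,CT,17.5
1,left,1,MRI,16.5
1,left,2,CT,19.4
1,left,2,MRI,16.2
2,right,1,CT,-9.4
2,right,1,MRI,-0.6
2,right,2,CT,-5.3
2,right,2,MRI,-4.1
2,left,1,CT,-4.7
2,left,1,MRI,NA
2,left,2,CT,-0.2
2,left,2,MRI,NA
3,right,1,CT,15.2
3,right,1,MRI,14.1
3,right,2,CT,13.1
3,right,2,MRI,14.2
3,left,1,CT,18.2
3,left,1,MRI,18.8
3,left,2,CT,18.3
3,left,2,MRI,21.4
4,right,1,CT,12.4
4,right,1,MRI,8.9
4,right,2,CT,15.1
4,right,2,MRI,11.4
4,left,1,CT,9.5
4,left,1,MRI,13
4,left,2,CT,13.5
4,left,2,MRI,16.6
5,right,1,CT,7.6
5,right,1,MRI,10.9
5,right,2,CT,4.6
5,right,2,MRI,9.5
5,left,1,CT,10
5,left,1,MRI,12.5
5,left,2,CT,10.2
5,left,2,MRI,8.3
6,right,1,CT,10.5
6,right,1,MRI,11.2
6,right,2,CT,9.1
6,right,2,MRI,6.5
6,left,1,CT,4.7
6,left,1,MRI,7.3
6,left,2,CT,6.2
6,left,2,MRI,7.5
7,right,1,CT,11.9
7,right,1,MRI,8.6
7,right,2,CT,8.1
7,right,2,MRI,5.5
7,left,1,CT,9.1
7,left,1,MRI,10.4
7,left,2,CT,8.1
7,left,2,MRI,11.6
8,right,1,CT,20.7
8,right,1,MRI,18.6
8,right,2,CT,21.4
8,right,2,MRI,19.3
8,left,1,CT,28.2
8,left,1,MRI,27.4
8,left,2,CT,27
8,left,2,MRI,24.2
9,right,1,CT,5.4
9,right,1,MRI,7.6
9,right,2,CT,8
9,right,2,MRI,8.2
9,left,1,CT,9
9,left,1,MRI,6.8
9,left,2,CT,10.6
9,left,2,MRI,11.4
10,right,1,CT,1.9
10,right,1,MRI,0.2
10,right,2,CT,1
10,right,2,MRI,2.8
10,left,1,CT,2.8
10,left,1,MRI,3.2
10,left,2,CT,5.8
10,left,2,MRI,6.1
11,right,1,CT,5.4
11,right,1,MRI,3.3
11,right,2,CT,0.2
11,right,2,MRI,0.8
11,left,1,CT,20.8
11,left,1,MRI,20.6
11,left,2,CT,18.3
11,left,2,MRI,19
12,right,1,CT,-7.2
12,right,1,MRI,-4.1
12,right,2,CT,-2.3
12,right,2,MRI,-7.2
12,left,1,CT,-15.8
12,left,1,MRI,-16.4
12,left,2,CT,-13.2
12,left,2,MRI,-16
13,right,1,CT,7.4
13,right,1,MRI,7.4
13,right,2,CT,10
13,right,2,MRI,8.5
13,left,1,CT,3.3
13,left,1,MRI,3.1
13,left,2,CT,4.8
13,left,2,MRI,6.2
14,right,1,CT,14.8
14,right,1,MRI,15.8
14,right,2,CT,14.5
14,right,2,MRI,13
14,left,1,CT,17.1
14,left,1,MRI,13.8
14,left,2,CT,17.1
14,left,2,MRI,18.2
15,right,1,CT,10.1
15,right,1,MRI,14.4
15,right,2,CT,14.4
15,right,2,MRI,17.6
15,left,1,CT,2.6
15,left,1,MRI,7.3
15,left,2,CT,5.4
15,left,2,MRI,12.2
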