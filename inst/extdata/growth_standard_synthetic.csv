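age,sex,height_cm,median_bmi
0,male,49.9,13.4
1,male,75.7,17.2
2,male,87.1,16.6
3,male,96.1,16.1
4,male,103.3,15.8
5,male,110.0,15.5
6,male,116.0,15.4
7,male,121.7,15.5
8,male,127.3,15.7
9,male,132.6,16.0
10,male,137.8,16.4
11,male,143.1,16.9
12,male,149.1,17.5
13,male,156.0,18.2
14,male,163.2,19.0
15,male,169.0,19.8
16,male,172.9,20.5
17,male,175.2,21.1
18,male,176.5,21.7
0,female,49.1,13.3
1,female,74.0,16.8
2,female,85.7,16.3
3,female,95.1,15.8
4,female,102.7,15.5
5,female,109.4,15.3
6,female,115.1,15.3
7,female,120.8,15.4
8,female,126.6,15.7
9,female,132.5,16.1
10,female,138.6,16.6
11,female,145.0,17.2
12,female,151.2,18.0
13,female,155.8,18.8
14,female,158.7,19.6
15,female,161.7,20.2
16,female,162.5,20.7
17,female,162.9,21.0
18,female,163.1,21.3
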