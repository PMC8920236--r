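Conductivity,Temperature,Salinity
0.13094402,5.0,0.10000000
0.25789140,5.0,0.20000000
0.62611349,5.0,0.50000000
1.21635040,5.0,1.00000000
1.78922905,5.0,1.50000000
2.23875379,5.0,1.90000000
2.33900455,5.0,1.99000000
2.35012486,5.0,2.00000000
2.36145595,5.0,2.01000000
2.46133186,5.0,2.10000000
3.44594054,5.0,3.00000000
5.56524859,5.0,5.00000000
8.62667482,5.0,8.00000000
12.56389956,5.0,12.00000000
18.25672271,5.0,18.00000000
24.65951828,5.0,25.00000000
29.10431275,5.0,30.00000000
33.45428897,5.0,35.00000000
37.71625541,5.0,40.00000000
0.15008577,10.0,0.10000000
0.29561372,10.0,0.20000000
0.71764399,10.0,0.50000000
1.39364363,10.0,1.00000000
2.04933750,10.0,1.50000000
2.56363247,10.0,1.90000000
2.67830643,10.0,1.99000000
2.69102618,10.0,2.00000000
2.70384620,10.0,2.01000000
2.81809002,10.0,2.10000000
3.94397359,10.0,3.00000000
6.36555474,10.0,5.00000000
9.86012128,10.0,8.00000000
14.34913394,10.0,12.00000000
20.83043066,10.0,18.00000000
28.10824737,10.0,25.00000000
33.15395975,10.0,30.00000000
38.08743414,10.0,35.00000000
42.91713753,10.0,40.00000000
0.17006809,15.0,0.10000000
0.33499419,15.0,0.20000000
0.81319159,15.0,0.50000000
1.57868558,15.0,1.00000000
2.32077723,15.0,1.50000000
2.90263458,15.0,1.90000000
3.03235253,15.0,1.99000000
3.04672700,15.0,1.99999059
3.06111019,15.0,2.01000000
3.19034013,15.0,2.10000000
4.46356101,15.0,3.00000000
7.20030773,15.0,5.00000000
11.14634255,15.0,8.00000000
16.21029391,15.0,12.00000000
23.51285249,15.0,18.00000000
31.70179604,15.0,25.00000000
37.37311102,15.0,30.00000000
42.91400008,15.0,35.00000000
48.33468191,15.0,40.00000000
0.19080363,20.0,0.10000000
0.37586059,20.0,0.20000000
0.91233884,20.0,0.50000000
1.77066955,20.0,1.00000000
2.60236675,20.0,1.50000000
3.25428593,20.0,1.90000000
3.39960351,20.0,1.99000000
3.41558140,20.0,2.00000000
3.43169456,20.0,2.01000000
3.57646394,20.0,2.10000000
5.00244741,20.0,3.00000000
8.06589216,20.0,5.00000000
12.47978012,20.0,8.00000000
18.13935153,20.0,12.00000000
26.29243477,20.0,18.00000000
35.42468985,20.0,25.00000000
41.74358737,20.0,30.00000000
47.91316841,20.0,35.00000000
53.94548820,20.0,40.00000000
0.21220742,25.0,0.10000000
0.41804532,25.0,0.20000000
1.01467952,25.0,0.50000000
1.96881058,25.0,1.00000000
2.89295640,25.0,1.50000000
3.61715211,25.0,1.90000000
3.77856160,25.0,1.99000000
3.79619025,25.0,1.99984712
3.81408798,25.0,2.01000000
3.97488702,25.0,2.10000000
5.55843864,25.0,3.00000000
8.95879149,25.0,5.00000000
13.85502891,25.0,8.00000000
20.12850350,25.0,12.00000000
29.15795475,25.0,18.00000000
39.26191100,25.0,25.00000000
46.24775927,25.0,30.00000000
53.06476645,25.0,35.00000000
59.72690097,25.0,40.00000000
0.23419694,30.0,0.10000000
0.46138567,30.0,0.20000000
1.11981922,30.0,0.50000000
2.17234651,30.0,1.00000000
3.19142999,30.0,1.50000000
3.98984051,30.0,1.90000000
4.16777270,30.0,1.99000000
4.18709317,30.0,2.00000000
4.20682323,30.0,2.01000000
4.38408092,30.0,2.10000000
6.12940473,30.0,3.00000000
9.87559258,30.0,5.00000000
15.26684394,30.0,8.00000000
22.17017973,30.0,12.00000000
32.09853026,30.0,18.00000000
43.19890687,30.0,25.00000000
50.86855211,30.0,30.00000000
58.34926722,30.0,35.00000000
65.65700257,30.0,40.00000000
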