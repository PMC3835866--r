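week,sex,percentile,grams
24,female,3,446.1
24,female,5,476.5
24,female,10,523.4
24,female,25,601.7
24,female,50,688.7
24,female,75,775.7
24,female,90,854
24,female,95,900.9
24,female,97,931.3
25,female,3,525.3
25,female,5,561.2
25,female,10,616.4
25,female,25,708.6
25,female,50,811
25,female,75,913.5
25,female,90,1005.7
25,female,95,1060.9
25,female,97,1096.8
26,female,3,614.7
26,female,5,656.7
26,female,10,721.2
26,female,25,829.2
26,female,50,949
26,female,75,1068.9
26,female,90,1176.9
26,female,95,1241.4
26,female,97,1283.4
27,female,3,714.2
27,female,5,763
27,female,10,838
27,female,25,963.4
27,female,50,1102.7
27,female,75,1242
27,female,90,1367.3
27,female,95,1442.4
27,female,97,1491.1
28,female,3,823.3
28,female,5,879.5
28,female,10,966
28,female,25,1110.5
28,female,50,1271.1
28,female,75,1431.7
28,female,90,1576.2
28,female,95,1662.7
28,female,97,1718.9
29,female,3,941
29,female,5,1005.2
29,female,10,1104.1
29,female,25,1269.3
29,female,50,1452.8
29,female,75,1636.3
29,female,90,1801.5
29,female,95,1900.4
29,female,97,1964.6
30,female,3,1065.8
30,female,5,1138.5
30,female,10,1250.4
30,female,25,1437.5
30,female,50,1645.4
30,female,75,1853.2
30,female,90,2040.3
30,female,95,2152.3
30,female,97,2225
31,female,3,1195.5
31,female,5,1277.1
31,female,10,1402.7
31,female,25,1612.5
31,female,50,1845.7
31,female,75,2078.8
31,female,90,2288.7
31,female,95,2414.3
31,female,97,2495.9
32,female,3,1327.8
32,female,5,1418.4
32,female,10,1557.9
32,female,25,1791
32,female,50,2050
32,female,75,2309
32,female,90,2542.1
32,female,95,2681.6
32,female,97,2772.2
33,female,3,1460.2
33,female,5,1559.8
33,female,10,1713.2
33,female,25,1969.5
33,female,50,2254.3
33,female,75,2539.1
33,female,90,2795.4
33,female,95,2948.8
33,female,97,3048.5
34,female,3,1589.9
34,female,5,1698.4
34,female,10,1865.4
34,female,25,2144.5
34,female,50,2454.6
34,female,75,2764.7
34,female,90,3043.8
34,female,95,3210.8
34,female,97,3319.3
35,female,3,1714.7
35,female,5,1831.6
35,female,10,2011.8
35,female,25,2312.8
35,female,50,2647.2
35,female,75,2981.6
35,female,90,3282.6
35,female,95,3462.7
35,female,97,3579.7
36,female,3,1832.4
36,female,5,1957.4
36,female,10,2149.9
36,female,25,2471.5
36,female,50,2828.9
36,female,75,3186.3
36,female,90,3507.9
36,female,95,3700.4
36,female,97,3825.4
37,female,3,1941.5
37,female,5,2073.9
37,female,10,2277.9
37,female,25,2618.7
37,female,50,2997.3
37,female,75,3376
37,female,90,3716.8
37,female,95,3920.8
37,female,97,4053.2
38,female,3,2041
38,female,5,2180.2
38,female,10,2394.6
38,female,25,2752.9
38,female,50,3151
38,female,75,3549
38,female,90,3907.3
38,female,95,4121.7
38,female,97,4260.9
39,female,3,2130.3
39,female,5,2275.7
39,female,10,2499.5
39,female,25,2873.5
39,female,50,3289
39,female,75,3704.5
39,female,90,4078.4
39,female,95,4302.2
39,female,97,4447.6
40,female,3,2209.6
40,female,5,2360.3
40,female,10,2592.5
40,female,25,2980.3
40,female,50,3411.3
40,female,75,3842.2
40,female,90,4230.1
40,female,95,4462.2
40,female,97,4613
41,female,3,2279
41,female,5,2434.5
41,female,10,2673.9
41,female,25,3073.9
41,female,50,3518.4
41,female,75,3962.9
41,female,90,4363
41,female,95,4602.4
41,female,97,4757.9
42,female,3,2339.1
42,female,5,2498.7
42,female,10,2744.4
42,female,25,3155
42,female,50,3611.3
42,female,75,4067.5
42,female,90,4478.1
42,female,95,4723.8
42,female,97,4883.4
43,female,3,2390.8
43,female,5,2553.9
43,female,10,2805
43,female,25,3224.7
43,female,50,3691
43,female,75,4157.3
43,female,90,4577
43,female,95,4828.2
43,female,97,4991.3
44,female,3,2434.8
44,female,5,2600.9
44,female,10,2856.7
44,female,25,3284.1
44,female,50,3759
44,female,75,4233.9
44,female,90,4661.3
44,female,95,4917.1
44,female,97,5083.2
24,male,3,434.5
24,male,5,469.6
24,male,10,523.5
24,male,25,613.7
24,male,50,713.9
24,male,75,814.1
24,male,90,904.3
24,male,95,958.3
24,male,97,993.3
25,male,3,511.7
25,male,5,552.9
25,male,10,616.5
25,male,25,722.7
25,male,50,840.7
25,male,75,958.7
25,male,90,1064.9
25,male,95,1128.5
25,male,97,1169.8
26,male,3,598.7
26,male,5,647
26,male,10,721.4
26,male,25,845.7
26,male,50,983.8
26,male,75,1121.9
26,male,90,1246.1
26,male,95,1320.5
26,male,97,1368.8
27,male,3,695.6
27,male,5,751.8
27,male,10,838.2
27,male,25,982.6
27,male,50,1143
27,male,75,1303.4
27,male,90,1447.8
27,male,95,1534.2
27,male,97,1590.4
28,male,3,801.9
28,male,5,866.6
28,male,10,966.2
28,male,25,1132.7
28,male,50,1317.6
28,male,75,1502.5
28,male,90,1669
28,male,95,1768.6
28,male,97,1833.3
29,male,3,916.5
29,male,5,990.5
29,male,10,1104.3
29,male,25,1294.6
29,male,50,1506
29,male,75,1717.3
29,male,90,1907.6
29,male,95,2021.4
29,male,97,2095.4
30,male,3,1038
30,male,5,1121.8
30,male,10,1250.7
30,male,25,1466.2
30,male,50,1705.6
30,male,75,1945
30,male,90,2160.4
30,male,95,2289.4
30,male,97,2373.1
31,male,3,1164.4
31,male,5,1258.3
31,male,10,1403
31,male,25,1644.7
31,male,50,1913.2
31,male,75,2181.7
31,male,90,2423.4
31,male,95,2568.1
31,male,97,2662
32,male,3,1293.3
32,male,5,1397.6
32,male,10,1558.3
32,male,25,1826.7
32,male,50,2125
32,male,75,2423.3
32,male,90,2691.7
32,male,95,2852.4
32,male,97,2956.7
33,male,3,1422.2
33,male,5,1536.9
33,male,10,1713.6
33,male,25,2008.8
33,male,50,2336.8
33,male,75,2664.8
33,male,90,2960
33,male,95,3136.7
33,male,97,3251.4
34,male,3,1548.6
34,male,5,1673.5
34,male,10,1865.8
34,male,25,2187.3
34,male,50,2544.4
34,male,75,2901.6
34,male,90,3223
34,male,95,3415.4
34,male,97,3540.3
35,male,3,1670
35,male,5,1804.8
35,male,10,2012.2
35,male,25,2358.9
35,male,50,2744
35,male,75,3129.2
35,male,90,3475.8
35,male,95,3683.3
35,male,97,3818
36,male,3,1784.7
36,male,5,1928.7
36,male,10,2150.3
36,male,25,2520.8
36,male,50,2932.4
36,male,75,3344
36,male,90,3714.4
36,male,95,3936.1
36,male,97,4080.1
37,male,3,1890.9
37,male,5,2043.5
37,male,10,2278.4
37,male,25,2670.9
37,male,50,3107
37,male,75,3543.1
37,male,90,3935.6
37,male,95,4170.5
37,male,97,4323.1
38,male,3,1987.9
38,male,5,2148.2
38,male,10,2395.2
38,male,25,2807.8
38,male,50,3266.2
38,male,75,3724.7
38,male,90,4137.3
38,male,95,4384.2
38,male,97,4544.6
39,male,3,2074.9
39,male,5,2242.3
39,male,10,2500.1
39,male,25,2930.8
39,male,50,3409.3
39,male,75,3887.8
39,male,90,4318.5
39,male,95,4576.3
39,male,97,4743.7
40,male,3,2152.1
40,male,5,2325.7
40,male,10,2593
40,male,25,3039.7
40,male,50,3536.1
40,male,75,4032.4
40,male,90,4479.1
40,male,95,4746.5
40,male,97,4920.1
41,male,3,2219.7
41,male,5,2398.7
41,male,10,2674.5
41,male,25,3135.2
41,male,50,3647.1
41,male,75,4159
41,male,90,4619.8
41,male,95,4895.5
41,male,97,5074.6
42,male,3,2278.3
42,male,5,2462
42,male,10,2745.1
42,male,25,3218
42,male,50,3743.4
42,male,75,4268.8
42,male,90,4741.7
42,male,95,5024.7
42,male,97,5208.5
43,male,3,2328.6
43,male,5,2516.4
43,male,10,2805.7
43,male,25,3289
43,male,50,3826.1
43,male,75,4363.1
43,male,90,4846.4
43,male,95,5135.7
43,male,97,5323.6
44,male,3,2371.4
44,male,5,2562.8
44,male,10,2857.4
44,male,25,3349.6
44,male,50,3896.5
44,male,75,4443.4
44,male,90,4935.7
44,male,95,5230.3
44,male,97,5421.6
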