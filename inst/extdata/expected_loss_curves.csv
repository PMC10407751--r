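clinic_id,overbooked,expected_loss
1,1,148.17
1,2,120.94
1,3,98.39
1,4,82.83
1,5,77.39
1,6,74.28
1,7,84.39
1,8,105.39
1,9,134.17
1,10,166.83
2,1,250.41
2,2,200.33
2,3,158.77
2,4,127.87
2,5,116.15
2,6,130.00
2,7,160.90
2,8,208.85
2,9,271.72
2,10,334.59
3,1,239.69
3,2,195.00
3,3,162.50
3,4,142.19
3,5,130.00
3,6,134.06
3,7,162.50
3,8,219.38
3,9,280.31
3,10,345.31
4,1,53.91
4,2,44.13
4,3,35.65
4,4,29.35
4,5,27.39
4,6,31.52
4,7,40.43
4,8,53.26
4,9,66.96
4,10,81.09
5,1,68.10
5,2,54.30
5,3,42.30
5,4,33.90
5,5,30.30
5,6,29.10
5,7,33.90
5,8,40.50
5,9,53.10
5,10,66.90
6,1,445.98
6,2,359.02
6,3,311.34
6,4,274.88
6,5,283.29
6,6,319.76
6,7,367.44
6,8,420.73
6,9,490.85
6,10,589.02
7,1,305.74
7,2,245.56
7,3,199.81
7,4,173.33
7,5,166.11
7,6,168.52
7,7,175.74
7,8,192.59
7,9,223.89
7,10,279.26
8,1,475.30
8,2,384.18
8,3,342.31
8,4,334.93
8,5,376.79
8,6,458.06
8,7,578.73
8,8,714.18
8,9,859.48
8,10,1009.70
9,1,244.61
9,2,193.29
9,3,159.08
9,4,135.13
9,5,145.39
9,6,159.08
9,7,183.03
9,8,227.50
9,9,278.82
9,10,340.39
10,1,439.25
10,2,355.25
10,3,299.25
10,4,260.75
10,5,229.25
10,6,239.75
10,7,278.25
10,8,334.25
10,9,411.25
10,10,505.75
11,1,58.31
11,2,49.65
11,3,42.25
11,4,39.08
11,5,39.30
11,6,41.62
11,7,44.79
11,8,51.34
11,9,62.96
11,10,76.69
12,1,118.05
12,2,87.80
12,3,71.78
12,4,67.63
12,5,78.90
12,6,92.54
12,7,110.93
12,8,136.44
12,9,164.32
12,10,196.95
13,1,304.27
13,2,246.77
13,3,232.40
13,4,246.77
13,5,285.10
13,6,352.19
13,7,428.85
13,8,519.90
13,9,620.52
13,10,730.73
14,1,733.80
14,2,602.93
14,3,528.15
14,4,481.41
14,5,490.76
14,6,565.54
14,7,668.37
14,8,789.89
14,9,986.20
14,10,1201.20
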