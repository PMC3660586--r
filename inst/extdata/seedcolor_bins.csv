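# Binned RGB seed-coat colour distributions of the six generations of the
# white x black sesame reference cross, three field replications.
# bin_low is the lower edge of a 10-unit RGB class; count is plants.
replication,generation,bin_low,count
1,P1,120,1
1,P1,130,14
1,P1,140,9
1,P1,150,1
1,P2,20,3
1,P2,30,16
1,P2,40,7
1,P2,50,2
1,F1,20,4
1,F1,30,8
1,F1,40,12
1,F1,50,2
1,F1,60,1
1,BC1,20,2
1,BC1,30,12
1,BC1,40,52
1,BC1,50,12
1,BC1,60,16
1,BC1,70,6
1,BC1,80,14
1,BC1,90,21
1,BC1,100,17
1,BC1,110,24
1,BC1,120,19
1,BC1,130,10
1,BC1,140,8
1,BC2,20,16
1,BC2,30,55
1,BC2,40,91
1,BC2,50,20
1,BC2,60,7
1,F2,20,12
1,F2,30,65
1,F2,40,78
1,F2,50,29
1,F2,60,26
1,F2,70,25
1,F2,80,17
1,F2,90,19
1,F2,100,8
1,F2,110,20
1,F2,120,5
1,F2,130,2
1,F2,140,1
2,P1,120,3
2,P1,130,13
2,P1,140,9
2,P1,150,3
2,P2,20,3
2,P2,30,17
2,P2,40,8
2,P2,50,2
2,F1,20,3
2,F1,30,9
2,F1,40,13
2,F1,50,4
2,F1,60,1
2,BC1,20,2
2,BC1,30,10
2,BC1,40,36
2,BC1,50,7
2,BC1,60,14
2,BC1,70,9
2,BC1,80,10
2,BC1,90,14
2,BC1,100,21
2,BC1,110,22
2,BC1,120,22
2,BC1,130,17
2,BC1,140,7
2,BC1,150,1
2,BC2,20,13
2,BC2,30,57
2,BC2,40,90
2,BC2,50,18
2,BC2,60,7
2,BC2,70,1
2,F2,20,12
2,F2,30,69
2,F2,40,69
2,F2,50,28
2,F2,60,26
2,F2,70,19
2,F2,80,17
2,F2,90,19
2,F2,100,7
2,F2,110,14
2,F2,120,7
2,F2,130,1
2,F2,140,1
3,P1,120,3
3,P1,130,17
3,P1,140,8
3,P1,150,2
3,P2,20,2
3,P2,30,14
3,P2,40,7
3,P2,50,2
3,F1,20,3
3,F1,30,9
3,F1,40,13
3,F1,50,3
3,F1,60,1
3,BC1,20,1
3,BC1,30,11
3,BC1,40,37
3,BC1,50,7
3,BC1,60,7
3,BC1,70,6
3,BC1,80,9
3,BC1,90,18
3,BC1,100,21
3,BC1,110,20
3,BC1,120,10
3,BC1,130,5
3,BC1,140,3
3,BC2,20,12
3,BC2,30,53
3,BC2,40,91
3,BC2,50,16
3,BC2,60,8
3,F2,20,14
3,F2,30,64
3,F2,40,90
3,F2,50,29
3,F2,60,14
3,F2,70,28
3,F2,80,22
3,F2,90,19
3,F2,100,13
3,F2,110,16
3,F2,120,8
3,F2,130,5
3,F2,140,1
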