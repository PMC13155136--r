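treatment,replicate,cells_per_well,n_wells,n_negative
0Gy,1,1,12,10
0Gy,1,2,12,7
0Gy,1,4,12,1
0Gy,1,8,12,0
0Gy,1,16,12,0
0Gy,1,32,12,0
0Gy,1,64,12,0
0Gy,1,128,12,0
0Gy,2,1,12,11
0Gy,2,2,12,7
0Gy,2,4,12,0
0Gy,2,8,12,0
0Gy,2,16,12,0
0Gy,2,32,12,0
0Gy,2,64,12,0
0Gy,2,128,12,0
0Gy,3,1,12,10
0Gy,3,2,12,12
0Gy,3,4,12,2
0Gy,3,8,12,0
0Gy,3,16,12,0
0Gy,3,32,12,0
0Gy,3,64,12,0
0Gy,3,128,12,0
2Gy,1,1,12,12
2Gy,1,2,12,11
2Gy,1,4,12,7
2Gy,1,8,12,1
2Gy,1,16,12,0
2Gy,1,32,12,0
2Gy,1,64,12,0
2Gy,1,128,12,0
2Gy,2,1,12,11
2Gy,2,2,12,12
2Gy,2,4,12,7
2Gy,2,8,12,2
2Gy,2,16,12,0
2Gy,2,32,12,0
2Gy,2,64,12,0
2Gy,2,128,12,0
2Gy,3,1,12,12
2Gy,3,2,12,9
2Gy,3,4,12,7
2Gy,3,8,12,2
2Gy,3,16,12,0
2Gy,3,32,12,0
2Gy,3,64,12,0
2Gy,3,128,12,0
4Gy,1,1,12,12
4Gy,1,2,12,12
4Gy,1,4,12,9
4Gy,1,8,12,8
4Gy,1,16,12,8
4Gy,1,32,12,2
4Gy,1,64,12,0
4Gy,1,128,12,0
4Gy,2,1,12,12
4Gy,2,2,12,12
4Gy,2,4,12,9
4Gy,2,8,12,10
4Gy,2,16,12,4
4Gy,2,32,12,2
4Gy,2,64,12,0
4Gy,2,128,12,0
4Gy,3,1,12,12
4Gy,3,2,12,12
4Gy,3,4,12,11
4Gy,3,8,12,9
4Gy,3,16,12,5
4Gy,3,32,12,1
4Gy,3,64,12,0
4Gy,3,128,12,0
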