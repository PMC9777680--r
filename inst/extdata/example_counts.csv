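id,otu_01,otu_02,otu_03,otu_04,otu_05,otu_06,otu_07,otu_08,otu_09,otu_10,otu_11,otu_12
subject_01,332,246,807,541,1540,12,194,26,85,86,103,12
subject_02,280,130,192,668,961,88,351,578,70,564,112,20
subject_03,387,638,1154,117,946,113,55,55,41,269,178,28
subject_04,1083,1147,393,358,464,41,79,83,13,124,58,92
subject_05,351,681,87,109,313,256,49,46,45,172,1618,300
subject_06,444,982,707,299,505,44,55,64,11,558,96,273
subject_07,995,1446,46,123,385,42,31,306,89,128,286,67
subject_08,1989,206,398,527,184,40,51,30,85,229,85,81
subject_09,268,493,834,598,323,99,679,77,347,226,123,7
subject_10,199,613,1369,554,842,79,127,23,19,49,87,42
subject_11,621,74,240,710,1591,188,87,148,53,229,36,75
subject_12,2193,740,96,195,316,14,41,167,61,12,13,127
subject_13,440,226,495,340,1947,100,115,119,37,85,60,26
subject_14,243,98,465,1032,1305,58,196,33,232,83,76,110
subject_15,115,150,609,1360,649,25,448,243,206,83,30,82
subject_16,571,1717,170,342,495,183,106,25,107,53,73,72
subject_17,192,479,399,319,987,516,184,220,176,381,77,14
subject_18,468,414,651,1046,623,90,88,108,56,92,256,113
subject_19,921,704,914,1006,98,16,25,94,50,169,38,41
subject_20,61,842,926,1275,579,91,57,31,59,28,15,1
subject_21,1208,759,221,177,203,232,216,198,122,70,113,492
subject_22,2496,160,300,504,128,38,16,1,78,100,73,149
subject_23,354,386,454,269,1972,138,64,64,78,58,55,59
subject_24,1017,1665,585,208,85,13,29,210,101,5,36,110
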