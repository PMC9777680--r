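"id","y"
"subject_01",0.4259
"subject_02",-0.5428
"subject_03",0.9935
"subject_04",0.5856
"subject_05",0.1321
"subject_06",0.0646
"subject_07",-0.0417
"subject_08",1.5916
"subject_09",-0.1521
"subject_10",-0.8211
"subject_11",0.3805
"subject_12",1.5332
"subject_13",-2.524
"subject_14",-1.7562
"subject_15",-1.3137
"subject_16",-0.5717
"subject_17",-0.6716
"subject_18",-0.8386
"subject_19",0.1952
"subject_20",-0.5679
"subject_21",0.0036
"subject_22",0.196
"subject_23",-2.4404
"subject_24",-0.4617
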