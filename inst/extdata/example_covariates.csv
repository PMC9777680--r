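"id","sex","age"
"subject_01","M",35
"subject_02","F",32
"subject_03","F",29
"subject_04","F",33
"subject_05","F",34
"subject_06","F",39
"subject_07","F",40
"subject_08","F",39
"subject_09","M",31
"subject_10","F",33
"subject_11","F",43
"subject_12","F",44
"subject_13","M",52
"subject_14","F",55
"subject_15","M",66
"subject_16","F",59
"subject_17","F",55
"subject_18","M",57
"subject_19","F",55
"subject_20","M",60
"subject_21","M",57
"subject_22","M",63
"subject_23","F",63
"subject_24","M",57
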