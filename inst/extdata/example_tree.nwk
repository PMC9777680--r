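((otu_08:0.154,otu_05:0.994):0.054,((((otu_01:0.544,otu_12:0.13):0.712,(otu_06:0.125,otu_07:0.359):0.051):0.09,((otu_03:0.529,otu_10:0.661):0.86,otu_04:0.513):0.811):0.688,(otu_02:0.505,(otu_09:0.198,otu_11:0.447):0.113):0.955):0.857);
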