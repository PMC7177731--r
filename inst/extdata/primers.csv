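# Published gene-specific primers used for GS and PEPC probe
# amplification (product length in bp, annealing temperature in C).
probe,forward,reverse,length_bp,annealing_c
GS,GTTGGTCCCTCTGTTGGAATCTCTG,ATAAGCAGCAATGTGCTCATTGTGTCTC,571,56
PEPC,AAAGATGTTAGGAATCTTCACATGCTGCAAGA,GGGGCATATTCACTTGTTGGGTTCAGT,643,58
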