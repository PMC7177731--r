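# Published characterization of narrow-leafed lupin genome regions
# (scaffolds / BAC inserts) carrying GS and PEPC gene variants:
# GC percent, repeat-element content and CDS counts per region.
gene_variant,family,gene_id,scaffold,gc_percent,repeat_percent,repeat_bp,repeat_type,cds_nb
GS1a1,GS,gene6261,4_25,33.1,8.58,8584,Ty1/Copia,12
GS1a2,GS,gene27466,106,32.94,15.63,15635,Ty1/Copia;Gypsy/DIRS1;DNA,10
GS1a3,GS,gene24502,192,36.11,10.54,9282,Ty1/Copia;Gypsy/DIRS1;DNA,17
GS1b1,GS,gene19431,73,33,0,0,-,15
GS1b2,GS,gene17555,94_15,32.43,0.17,174,Ty1/Copia,16
GS1c1,GS,gene34907,11_68,30.56,9.19,2621,Ty1/Copia;DNA,3
GS1c2,GS,gene4422,13,31.89,7.2,7202,Ty1/Copia;DNA,15
GS2a1,GS,gene31805,45_213,33.88,9.96,9963,Ty1/Copia;Gypsy/DIRS1;DNA,12
GS2a2,GS,gene6462,186,32.66,7.73,7732,Ty1/Copia;Gypsy/DIRS1;DNA,12
PEPC1a,PEPC,gene23490,437,34.25,8.85,8852,Ty1/Copia;Gypsy/DIRS1,13
PEPC1b,PEPC,gene15450,74_10,32.28,1.88,1879,Ty1/Copia,13
PEPC1c,PEPC,gene12998,274,32.36,1.17,1169,Ty1/Copia,14
PEPC2a,PEPC,gene31196,110_41,32.41,3.63,3634,Ty1/Copia;Gypsy/DIRS1,14
PEPC2b,PEPC,gene9184,59_19,33.21,6.49,6748,Ty1/Copia;Gypsy/DIRS1,14
PEPC3a,PEPC,gene18605,9_1,33.97,5.17,1628,Ty1/Copia,3
PEPC3b,PEPC,gene7147,296,32.76,15.64,15641,Ty1/Copia;DNA,5
PEPC4,PEPC,no,12_32,33.76,8.64,8644,Ty1/Copia;Gypsy/DIRS1,16
PEPC5,PEPC,-,88_60,32.73,8.93,8933,Ty1/Copia;Gypsy/DIRS1;DNA,10
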