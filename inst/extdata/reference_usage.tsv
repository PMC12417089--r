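codon	weight
AAA	1
AAC	1
AAG	0.0523364485981308
AAT	0.045531197301855
ACA	1
ACC	0.0253623188405797
ACG	0.0235507246376812
ACT	0.0326086956521739
AGA	1
AGC	1
AGG	0.023972602739726
AGT	0.0188679245283019
ATA	1
ATC	0.0471869328493648
ATG	1
ATT	0.0381125226860254
CAA	1
CAC	1
CAG	0.0694698354661792
CAT	0.0457746478873239
CCA	1
CCC	0.0386965376782077
CCG	0.0264765784114053
CCT	0.0407331975560081
CGA	0.0256849315068493
CGC	0.0154109589041096
CGG	0.0205479452054795
CGT	0.0102739726027397
CTA	1
CTC	0.0213903743315508
CTG	0.017825311942959
CTT	0.017825311942959
GAA	1
GAC	1
GAG	0.0622641509433962
GAT	0.0511073253833049
GCA	1
GCC	0.0261194029850746
GCG	0.0335820895522388
GCT	0.0205223880597015
GGA	1
GGC	0.0420650095602294
GGG	0.017208413001912
GGT	0.0267686424474187
GTA	1
GTC	0.0175438596491228
GTG	0.0467836257309942
GTT	0.0233918128654971
TAC	1
TAT	0.0428816466552316
TCA	0.0207547169811321
TCC	0.0245283018867925
TCG	0.0188679245283019
TCT	0.0226415094339623
TGC	1
TGG	1
TGT	0.0522388059701493
TTA	0.0267379679144385
TTC	1
TTG	0.0124777183600713
TTT	0.0431778929188256
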