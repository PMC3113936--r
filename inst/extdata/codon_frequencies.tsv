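# Default sense-codon frequency table used by generate_random_gene().
# Approximate E. coli K-12 codon usage (standard published usage tables,
# per-1000 counts normalized to frequencies summing to 1). Editable:
# supply your own table with the same columns to override.
codon	frequency
TTT	0.02228245
TTC	0.01666165
TTA	0.01395162
TTG	0.01375088
CTT	0.01104085
CTC	0.01104085
CTA	0.00391448
CTG	0.05279534
ATT	0.03041253
ATC	0.02519321
ATA	0.00441634
ATG	0.02800361
GTT	0.01836796
GTC	0.01535682
GTA	0.01094048
GTG	0.02649804
TCT	0.00853157
TCC	0.00863194
TCA	0.00722674
TCG	0.00893305
CCT	0.00702600
CCC	0.00552043
CCA	0.00843120
CCG	0.02328616
ACT	0.00903342
ACC	0.02348690
ACA	0.00712637
ACG	0.01445348
GCT	0.01535682
GCC	0.02559470
GCA	0.02017465
GCG	0.03372478
TAT	0.01626016
TAC	0.01224531
CAT	0.01294791
CAC	0.00973602
CAA	0.01535682
CAG	0.02890696
AAT	0.01776573
AAC	0.02178059
AAA	0.03372478
AAG	0.01033825
GAT	0.03221921
GAC	0.01917093
GAA	0.03954632
GAG	0.01786610
TGT	0.00521931
TGC	0.00642377
TGG	0.01525645
CGT	0.02097762
CGC	0.02208170
CGA	0.00361337
CGG	0.00542005
AGT	0.00883268
AGC	0.01615979
AGA	0.00210780
AGG	0.00120446
GGT	0.02479173
GGC	0.02970993
GGA	0.00802971
GGG	0.01114122
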