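# Default codon -> translation-rate class map (classes A, B, C correspond to
# the activation rates k_transA, k_transB, k_transC).
# Heuristic default: classes are assigned from E. coli codon-usage tertiles
# (frequent = A/fast, mid = B, rare = C/slow), standing in for directly
# measured per-codon rates, which are not shipped with the package. Editable:
# supply your own table (all 64 codons) to override. The class of the three
# stop codons is unused (the final codon fires the completion rate k_trans_f).
codon	class
TTT	A
TTC	B
TTA	B
TTG	B
CTT	B
CTC	B
CTA	C
CTG	A
ATT	A
ATC	A
ATA	C
ATG	A
GTT	B
GTC	B
GTA	B
GTG	A
TCT	C
TCC	C
TCA	C
TCG	C
CCT	C
CCC	C
CCA	C
CCG	A
ACT	C
ACC	A
ACA	C
ACG	B
GCT	B
GCC	A
GCA	A
GCG	A
TAT	B
TAC	B
CAT	B
CAC	C
CAA	B
CAG	A
AAT	B
AAC	A
AAA	A
AAG	B
GAT	A
GAC	A
GAA	A
GAG	B
TGT	C
TGC	C
TGG	B
CGT	A
CGC	A
CGA	C
CGG	C
AGT	C
AGC	B
AGA	C
AGG	C
GGT	A
GGC	A
GGA	C
GGG	B
TAA	A
TAG	A
TGA	A
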