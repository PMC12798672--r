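synonym,canonical
COI,cox1
CO1,cox1
COXI,cox1
COX1,cox1
cytochrome c oxidase subunit I,cox1
cytochrome c oxidase subunit 1,cox1
COII,cox2
CO2,cox2
COXII,cox2
COX2,cox2
cytochrome c oxidase subunit II,cox2
cytochrome c oxidase subunit 2,cox2
COIII,cox3
CO3,cox3
COXIII,cox3
COX3,cox3
cytochrome c oxidase subunit III,cox3
cytochrome c oxidase subunit 3,cox3
CYTB,cob
CYTOB,cob
CYB,cob
COB,cob
cytochrome b,cob
ND1,nad1
NADH1,nad1
NADH dehydrogenase subunit 1,nad1
ND2,nad2
NADH2,nad2
NADH dehydrogenase subunit 2,nad2
ND3,nad3
NADH3,nad3
NADH dehydrogenase subunit 3,nad3
ND4,nad4
NADH4,nad4
NADH dehydrogenase subunit 4,nad4
ND4L,nad4L
NADH4L,nad4L
NADH dehydrogenase subunit 4L,nad4L
ND5,nad5
NADH5,nad5
NADH dehydrogenase subunit 5,nad5
ND6,nad6
NADH6,nad6
NADH dehydrogenase subunit 6,nad6
ATP6,atp6
ATPASE6,atp6
ATPase 6,atp6
ATP synthase F0 subunit 6,atp6
ATP8,atp8
ATPASE8,atp8
ATPase 8,atp8
ATP synthase F0 subunit 8,atp8
16S,rrnL
16S rRNA,rrnL
16S ribosomal RNA,rrnL
l-rRNA,rrnL
lrRNA,rrnL
large subunit ribosomal RNA,rrnL
12S,rrnS
12S rRNA,rrnS
12S ribosomal RNA,rrnS
s-rRNA,rrnS
srRNA,rrnS
small subunit ribosomal RNA,rrnS
D-loop,CR
Dloop,CR
control region,CR
putative control region,CR
misc_feature putative control region,CR
A+T rich region,CR
AT-rich region,CR
non-coding region,CR
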