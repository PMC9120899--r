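fusion	drugs
BCR-ABL	imatinib;sunitinib;sorafenib
KDR-PDGFRA	imatinib;sunitinib;sorafenib
NCDN-PDGFRA	imatinib;sunitinib;sorafenib
COL1A1-PDGFB	imatinib;sunitinib;sorafenib
NIN-PDGFRB	imatinib;sunitinib;sorafenib
FGFR1-BCR	imatinib;sunitinib;sorafenib
CEP85L-ROS1	crizotinib;entrectinib;larotrectinib
GOPC-ROS1	crizotinib;entrectinib;larotrectinib
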