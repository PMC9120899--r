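sample	fusion
100058	BCR-ABL
100067	KDR-PDGFRA
100077	NCDN-PDGFRA
100156	COL1A1-PDGFB
100101	BCR-ABL
100101	KDR-PDGFRA
100106	
100142	NCDN-PDGFRA
100224	FGFR1-BCR
100237	CEP85L-ROS1
100240	NCDN-PDGFRA
I	NCDN-PDGFRA
II	GOPC-ROS1
IV	NIN-PDGFRB
V	
VIII	KDR-PDGFRA
IX	NCDN-PDGFRA
X	
XI	COL1A1-PDGFB
XI	NCDN-PDGFRA
XII	NIN-PDGFRB
#1	GOPC-ROS1
#3	NCDN-PDGFRA
#5	NCDN-PDGFRA
#7	CEP85L-ROS1
#13	NCDN-PDGFRA
#33	NCDN-PDGFRA
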