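gene	cell_type
AQP4	ast
GJA1	ast
SLC1A2	ast
GFAP	ast
ALDH1L1	ast
CLDN5	end
FLT1	end
APOLD1	end
PECAM1	end
TIE1	end
CCL4	mic
CX3CR1	mic
AIF1	mic
TMEM119	mic
P2RY12	mic
RELN	neu
SYT1	neu
SNAP25	neu
GRIN1	neu
VSTM2A	neu
PLP1	oli
UGT8	oli
ERMN	oli
MBP	oli
MOG	oli
PDGFRA	opc
CSPG4	opc
OLIG1	opc
SOX10	opc
GPR17	opc
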