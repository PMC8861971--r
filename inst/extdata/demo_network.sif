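ESR1 controls-expression-of GREB1 1
ESR1 controls-expression-of PGR 1
ESR1 controls-expression-of TFF1 1
ESR1 controls-expression-of CCND1 1
MYC controls-expression-of CDK4 1
MYC controls-expression-of CDKN1A -1
MYC controls-expression-of NPM1 1
E2F1 controls-expression-of CCNE2 1
E2F1 controls-expression-of PCNA 1
STAT3 controls-expression-of MUC1 1
STAT3 controls-expression-of SOCS3 1
STAT3 in-complex-with MUC1 1
MTOR controls-expression-of SREBF1 1
MTOR controls-expression-of HIF1A 1
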