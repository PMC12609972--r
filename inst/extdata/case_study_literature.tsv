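symbol	label	provenance
PRKCZ	UP	curated:cisplatin-reports
GRPR	UP	curated:cisplatin-reports
PLA2G2A	UP	curated:cisplatin-reports
PLCB4	UP	curated:cisplatin-reports
SARDH	UP	curated:cisplatin-reports
GABRR1	UP	curated:cisplatin-reports
CAMK4	UP	curated:cisplatin-reports
FANCC	UP	curated:cisplatin-reports
GRIA4	UP	curated:cisplatin-reports
HOXA5	DOWN	curated:cisplatin-reports
NFE2L2	DOWN	curated:cisplatin-reports
ABCC2	DOWN	curated:cisplatin-reports
UBB	SEG	curated:stable-controls
BCL2	SEG	curated:stable-controls
FAS	SEG	curated:stable-controls
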