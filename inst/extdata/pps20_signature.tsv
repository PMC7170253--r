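# name: PPS20
# description: 20-gene pancreatic ductal adenocarcinoma prognostic score; +1 genes are added, -1 genes subtracted, on log expression
gene	weight
ARNTL2	1
KANK1	-1
MAP4K4	1
LDHA	1
SLC20A1	1
TRIO	1
ZNF557	-1
EPS8	1
CBX7	-1
RAB7A	1
POLR3H	-1
STX16	1
PITPNA	-1
TFG	1
CADPS2	-1
ERRFI1	1
GSK3B	1
NDUFB2	-1
C2orf42	-1
MIA3	-1
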