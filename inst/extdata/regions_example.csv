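country,region
CHN,CHA
IND,IND
USA,GLN
DEU,GLN
FRA,GLN
GBR,GLN
JPN,GLN
RUS,GLN
BRA,LAM
MEX,LAM
ARG,LAM
COL,LAM
NGA,SSA
ETH,SSA
COD,SSA
ZAF,SSA
EGY,MAF
IRN,MAF
TUR,MAF
SAU,MAF
IDN,ASI
PAK,ASI
BGD,ASI
PHL,ASI
VNM,ASI
THA,ASI
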