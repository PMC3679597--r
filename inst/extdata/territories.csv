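country_code,synthetic
ABW,false
AFG,false
AGO,false
AIA,false
ALA,false
ALB,false
AND,false
ARE,false
ARG,false
ARM,false
ASM,false
ATA,false
ATF,false
ATG,false
AUS,false
AUT,false
AZE,false
BDI,false
BEL,false
BEN,false
BES,false
BFA,false
BGD,false
BGR,false
BHR,false
BHS,false
BIH,false
BLM,false
BLR,false
BLZ,false
BMU,false
BOL,false
BRA,false
BRB,false
BRN,false
BTN,false
BVT,false
BWA,false
CAF,false
CAN,false
CCK,false
CHE,false
CHL,false
CHN,false
CIV,false
CMR,false
COD,false
COG,false
COK,false
COL,false
COM,false
CPV,false
CRI,false
CUB,false
CUW,false
CXR,false
CYM,false
CYP,false
CZE,false
DEU,false
DJI,false
DMA,false
DNK,false
DOM,false
DZA,false
ECU,false
EGY,false
ERI,false
ESH,false
ESP,false
EST,false
ETH,false
FIN,false
FJI,false
FLK,false
FRA,false
FRO,false
FSM,false
GAB,false
GBR,false
GEO,false
GGY,false
GHA,false
GIB,false
GIN,false
GLP,false
GMB,false
GNB,false
GNQ,false
GRC,false
GRD,false
GRL,false
GTM,false
GUF,false
GUM,false
GUY,false
HKG,false
HMD,false
HND,false
HRV,false
HTI,false
HUN,false
IDN,false
IMN,false
IND,false
IOT,false
IRL,false
IRN,false
IRQ,false
ISL,false
ISR,false
ITA,false
JAM,false
JEY,false
JOR,false
JPN,false
KAZ,false
KEN,false
KGZ,false
KHM,false
KIR,false
KNA,false
KOR,false
KWT,false
LAO,false
LBN,false
LBR,false
LBY,false
LCA,false
LIE,false
LKA,false
LSO,false
LTU,false
LUX,false
LVA,false
MAC,false
MAF,false
MAR,false
MCO,false
MDA,false
MDG,false
MDV,false
MEX,false
MHL,false
MKD,false
MLI,false
MLT,false
MMR,false
MNE,false
MNG,false
MNP,false
MOZ,false
MRT,false
MSR,false
MTQ,false
MUS,false
MWI,false
MYS,false
MYT,false
NAM,false
NCL,false
NER,false
NFK,false
NGA,false
NIC,false
NIU,false
NLD,false
NOR,false
NPL,false
NRU,false
NZL,false
OMN,false
PAK,false
PAN,false
PCN,false
PER,false
PHL,false
PLW,false
PNG,false
POL,false
PRI,false
PRK,false
PRT,false
PRY,false
PSE,false
PYF,false
QAT,false
REU,false
ROU,false
RUS,false
RWA,false
SAU,false
SDN,false
SEN,false
SGP,false
SGS,false
SHN,false
SJM,false
SLB,false
SLE,false
SLV,false
SMR,false
SOM,false
SPM,false
SRB,false
SSD,false
STP,false
SUR,false
SVK,false
SVN,false
SWE,false
SWZ,false
SXM,false
SYC,false
SYR,false
TCA,false
TCD,false
TGO,false
THA,false
TJK,false
TKL,false
TKM,false
TLS,false
TON,false
TTO,false
TUN,false
TUR,false
TUV,false
TWN,false
TZA,false
UGA,false
UKR,false
UMI,false
URY,false
USA,false
UZB,false
VAT,false
VCT,false
VEN,false
VGB,false
VIR,false
VNM,false
VUT,false
WLF,false
WSM,false
YEM,false
ZAF,false
ZMB,false
ZWE,false
XAA,true
XAB,true
XAC,true
XAD,true
XAE,true
XAF,true
XAG,true
XAH,true
XAI,true
XAJ,true
XAK,true
XAL,true
XAM,true
XAN,true
XAO,true
XAP,true
XAQ,true
XAR,true
XAS,true
XAT,true
XAU,true
XAV,true
XAW,true
XAX,true
XAY,true
XAZ,true
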