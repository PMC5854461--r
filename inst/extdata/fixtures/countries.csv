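country_code,name
AFG,Afghanistan
BDI,Burundi
BEN,Benin
BFA,Burkina Faso
BGD,Bangladesh
BOL,Bolivia
BTN,Bhutan
CAF,Central African Republic
CIV,Côte d'Ivoire
CMR,Cameroon
COD,Democratic Republic of the Congo
COG,Congo (Brazzaville)
COM,Comoros
DJI,Djibouti
EGY,Egypt
ERI,Eritrea
ETH,Ethiopia
GHA,Ghana
GIN,Guinea
GMB,Gambia
GNB,Guinea-Bissau
HND,Honduras
HTI,Haiti
IDN,Indonesia
IND,India
IRQ,Iraq
KEN,Kenya
KGZ,Kyrgyzstan
KHM,Cambodia
LAO,Laos
LBR,Liberia
LKA,Sri Lanka
LSO,Lesotho
MDG,Madagascar
MLI,Mali
MMR,Myanmar
MNG,Mongolia
MOZ,Mozambique
MRT,Mauritania
MWI,Malawi
NER,Niger
NGA,Nigeria
NIC,Nicaragua
NPL,Nepal
PAK,Pakistan
PHL,Philippines
PNG,Papua New Guinea
PRK,North Korea
PSE,Palestine
RWA,Rwanda
SDN,Sudan
SEN,Senegal
SLB,Solomon Islands
SLE,Sierra Leone
SOM,Somalia
SSD,South Sudan
STP,São Tomé and Príncipe
TCD,Chad
TGO,Togo
TJK,Tajikistan
TLS,Timor-Leste
TZA,Tanzania
UGA,Uganda
UZB,Uzbekistan
VNM,Vietnam
YEM,Yemen
ZMB,Zambia
ZWE,Zimbabwe
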