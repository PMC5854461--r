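country_code,name,data_after_2012,mcpr_change,mcpr_change_lower,mcpr_change_upper,unmet_modern_change,unmet_modern_change_lower,unmet_modern_change_upper,demand_satisfied_change,demand_satisfied_change_lower,demand_satisfied_change_upper,users_change_millions,users_change_millions_lower,users_change_millions_upper
AFG,Afghanistan,TRUE,4·5,−1·3,11·1,−0·3,−6·6,5·8,5·9,−3·6,15·7,0·37,0·08,0·71
BGD,Bangladesh,TRUE,2·8,−7·9,13·1,−1·4,−7·6,5·8,2·4,−8·2,11·3,2·11,−1·76,5·82
BEN,Benin,TRUE,4·6,−0·4,11·1,−1·4,−8·3,5·8,8·2,−0·7,18·2,0·10,0·01,0·21
BTN,Bhutan,FALSE,3·7,−8·2,14·6,−1·6,−7·4,5·0,2·6,−7·4,11·0,0·02,0·00,0·03
BOL,Bolivia,FALSE,4·3,−8·6,17·3,−3·9,−15·2,7·8,5·1,−9·8,19·3,0·11,−0·08,0·30
BFA,Burkina Faso,TRUE,7·5,2·0,13·0,−0·2,−5·7,5·4,9·0,0·3,17·8,0·32,0·15,0·49
BDI,Burundi,TRUE,−1·8,−7·3,4·2,1·0,−4·3,6·4,−2·5,−10·3,5·2,0·04,−0·05,0·13
KHM,Cambodia,TRUE,5·3,−6·7,17·0,−2·3,−10·7,7·9,5·0,−9·2,17·8,0·22,−0·10,0·54
CMR,Cameroon,TRUE,6·1,−2·4,14·3,−0·6,−7·8,7·0,7·9,−5·0,19·6,0·29,−0·02,0·59
CAF,Central African Republic,FALSE,3·0,−2·9,12·5,−0·2,−6·9,6·9,5·0,−6·0,18·1,0·04,−0·02,0·14
TCD,Chad,TRUE,1·5,−0·2,3·9,0·6,−5·0,6·4,4·8,−1·3,12·2,0·05,0·01,0·11
COM,Comoros,FALSE,3·9,−3·2,14·0,−1·1,−7·8,6·1,5·6,−5·4,18·5,0·01,0·00,0·02
COG,Congo (Brazzaville),TRUE,3·5,−5·7,14·9,−3·2,−12·2,6·3,5·4,−8·1,20·2,0·04,−0·02,0·11
CIV,Côte d'Ivoire,TRUE,3·2,−0·9,7·8,0·4,−5·5,7·3,4·8,−3·2,12·9,0·10,−0·04,0·26
COD,Democratic Republic of the Congo,TRUE,2·3,−2·5,8·9,−0·4,−8·1,7·9,4·2,−4·8,14·5,0·43,−0·19,1·27
DJI,Djibouti,FALSE,5·1,−3·5,16·2,−1·2,−8·4,5·6,6·5,−6·1,19·6,0·01,0·00,0·02
EGY,Egypt,TRUE,0·9,−11·2,12·6,−0·1,−5·7,5·7,0·4,−9·4,9·1,1·03,−0·96,2·95
ERI,Eritrea,FALSE,2·0,−1·8,8·7,0·3,−6·3,7·3,3·8,−4·9,14·8,0·02,−0·01,0·08
ETH,Ethiopia,TRUE,6·9,−0·7,14·3,−3·3,−8·1,1·7,8·1,−0·7,16·6,1·66,0·58,2·76
GMB,Gambia,TRUE,0·7,−3·3,6·3,0·3,−5·7,6·5,1·3,−8·2,12·1,0·01,−0·01,0·02
GHA,Ghana,TRUE,5·0,−2·0,12·4,−3·3,−9·7,3·1,7·1,−2·1,16·7,0·28,0·00,0·58
GIN,Guinea,FALSE,1·3,−1·4,5·7,0·8,−4·9,7·4,3·1,−4·4,13·0,0·04,−0·02,0·13
GNB,Guinea-Bissau,TRUE,3·1,−3·1,11·6,0·8,−4·8,6·5,4·1,−7·5,16·5,0·01,0·00,0·03
HTI,Haiti,FALSE,4·3,−6·4,16·4,−3·2,−11·1,4·6,5·1,−7·1,18·1,0·13,−0·06,0·34
HND,Honduras,FALSE,1·5,−10·0,11·3,−1·2,−7·8,7·6,1·5,−9·7,9·8,0·11,−0·05,0·23
IND,India,TRUE,0·1,−8·6,9·0,−0·8,−5·8,4·8,0·8,−7·5,8·3,6·39,−15·53,29·01
IDN,Indonesia,TRUE,−1·1,−9·1,6·8,0·6,−3·4,5·4,−0·9,−7·9,5·0,0·43,−3·65,4·38
IRQ,Iraq,FALSE,3·4,−8·8,15·6,−1·2,−9·8,8·5,2·9,−11·6,15·5,0·49,−0·22,1·17
KEN,Kenya,TRUE,12·7,2·3,22·5,−7·8,−14·1,−1·1,11·9,2·1,20·9,1·26,0·58,1·89
KGZ,Kyrgyzstan,TRUE,4·1,−6·8,16·1,−0·6,−5·9,5·1,3·1,−9·1,14·0,0·06,−0·06,0·18
LAO,Laos,FALSE,5·4,−6·7,17·0,−2·7,−9·6,5·3,5·0,−7·6,15·5,0·15,−0·02,0·31
LSO,Lesotho,TRUE,7·4,−3·9,18·3,−4·3,−11·0,3·3,6·6,−4·2,16·1,0·03,0·00,0·05
LBR,Liberia,TRUE,6·5,−1·7,13·9,−1·7,−8·0,5·0,8·9,−2·6,18·9,0·05,0·00,0·10
MDG,Madagascar,FALSE,6·2,−5·1,18·5,−2·3,−9·2,5·1,6·2,−7·0,18·5,0·45,−0·03,0·98
MWI,Malawi,TRUE,9·7,−0·5,19·6,−6·1,−12·6,0·4,9·5,−0·4,18·9,0·48,0·21,0·73
MLI,Mali,TRUE,3·6,−1·3,10·0,−0·2,−6·0,5·6,6·7,−3·2,17·6,0·16,0·00,0·37
MRT,Mauritania,TRUE,4·3,−1·5,11·8,−0·4,−7·2,6·3,6·7,−2·9,17·5,0·03,0·00,0·08
MNG,Mongolia,TRUE,2·5,−9·5,14·0,−1·0,−7·7,6·6,2·0,−9·9,11·8,0·02,−0·04,0·08
MOZ,Mozambique,TRUE,15·7,4·6,23·0,−2·5,−7·9,3·3,19·2,5·5,28·7,0·77,0·28,1·09
MMR,Myanmar,TRUE,5·9,−4·9,16·5,−2·5,−8·4,3·4,5·2,−5·0,15·5,0·61,−0·32,1·53
NPL,Nepal,TRUE,5·4,−5·7,16·3,−4·4,−11·9,3·5,6·2,−5·5,17·0,0·62,−0·06,1·28
NIC,Nicaragua,FALSE,0·7,−8·7,7·8,−0·4,−4·4,5·2,0·5,−6·6,5·2,0·06,−0·04,0·13
NER,Niger,TRUE,2·6,−1·4,7·3,2·2,−2·1,7·4,1·9,−6·6,10·9,0·20,0·04,0·40
NGA,Nigeria,TRUE,2·7,−0·9,7·1,2·8,−2·3,8·2,2·4,−5·5,11·0,1·11,0·06,2·42
PRK,North Korea,FALSE,1·1,−10·1,11·1,−0·7,−6·9,6·7,1·0,−9·3,9·2,0·02,−0·47,0·45
PAK,Pakistan,TRUE,5·2,−2·2,13·1,−0·9,−7·3,6·1,5·4,−4·8,15·5,2·45,0·16,4·95
PSE,Palestine,TRUE,2·5,−9·3,14·9,−0·8,−8·9,8·3,2·0,−11·3,14·2,0·05,−0·02,0·12
PNG,Papua New Guinea,FALSE,1·9,−8·0,13·7,−1·0,−8·8,6·3,2·4,−10·1,15·7,0·06,−0·07,0·22
PHL,Philippines,TRUE,4·1,−7·7,16·5,−2·4,−11·1,7·5,4·3,−9·8,17·2,1·12,−0·77,3·12
RWA,Rwanda,TRUE,4·5,−5·5,14·3,−3·6,−10·0,3·2,5·4,−5·1,15·0,0·14,−0·01,0·29
STP,São Tomé and Príncipe,TRUE,6·0,−6·0,17·6,−5·0,−13·5,4·0,7·1,−5·8,18·9,0·00,0·00,0·01
SEN,Senegal,TRUE,6·4,0·0,14·3,−3·0,−8·2,2·4,10·8,0·9,21·2,0·20,0·05,0·40
SLE,Sierra Leone,TRUE,6·4,−0·4,13·5,−0·4,−6·3,5·8,9·5,−1·7,20·3,0·08,0·01,0·15
SLB,Solomon Islands,FALSE,1·8,−8·5,13·6,−0·4,−7·4,6·4,1·7,−11·1,14·5,0·00,−0·01,0·02
SOM,Somalia,FALSE,0·7,−0·4,3·9,0·2,−6·9,7·5,1·8,−1·5,9·2,0·01,0·00,0·06
SSD,South Sudan,FALSE,0·8,−0·7,4·1,0·4,−6·5,7·4,2·2,−2·3,10·0,0·03,0·00,0·10
LKA,Sri Lanka,FALSE,1·9,−11·0,14·3,−1·1,−10·7,9·4,1·6,−11·9,14·0,0·05,−0·39,0·48
SDN,Sudan,TRUE,2·3,−2·9,9·3,0·1,−6·5,6·7,3·9,−6·2,14·7,0·20,−0·11,0·65
TJK,Tajikistan,FALSE,3·5,−6·6,15·5,−0·5,−6·2,5·5,3·4,−9·5,15·8,0·09,−0·07,0·28
TLS,Timor-Leste,TRUE,3·1,−4·1,10·2,−1·7,−7·1,3·7,4·7,−5·0,14·5,0·00,−0·01,0·01
TGO,Togo,TRUE,4·6,−2·2,11·1,−1·9,−8·2,4·9,6·8,−3·1,15·9,0·08,0·00,0·16
UGA,Uganda,TRUE,7·3,0·0,14·5,−4·1,−9·6,1·5,8·8,0·0,17·5,0·66,0·27,1·04
TZA,Tanzania,TRUE,5·4,−3·8,14·6,−2·3,−8·2,3·7,6·2,−4·8,16·6,0·72,0·03,1·42
UZB,Uzbekistan,FALSE,1·2,−10·3,11·6,−0·4,−5·7,5·7,0·6,−8·5,8·3,0·30,−0·35,0·89
VNM,Vietnam,TRUE,−0·2,−11·2,9·3,0·4,−6·1,9·4,−0·5,−11·4,7·7,0·59,−1·49,2·37
YEM,Yemen,TRUE,5·4,−5·4,17·3,−2·2,−9·5,5·3,5·8,−7·0,19·2,0·40,−0·05,0·90
ZMB,Zambia,TRUE,6·3,−6·0,18·4,−3·9,−11·1,3·8,6·6,−5·8,18·3,0·29,0·01,0·56
ZWE,Zimbabwe,TRUE,5·6,−4·3,14·1,−2·7,−7·2,3·0,4·2,−4·2,10·8,0·35,0·08,0·56
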