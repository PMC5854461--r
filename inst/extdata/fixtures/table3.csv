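country_code,name,eval_year,gap_pp,gap_users_millions,attainment_pct,commitment
MOZ,Mozambique,2016,14·1,0·61,0,Yes
KEN,Kenya,2015,14·3,0·92,2,Yes
SLE,Sierra Leone,2016,7·7,0·08,3,Yes
TCD,Chad,2014,1·4,0·03,7,No
LBR,Liberia,2016,7·7,0·05,10,Yes
LSO,Lesotho,2014,7·5,0·02,11,No
MWI,Malawi,2015,8·4,0·21,11,Yes
SEN,Senegal,2015,3·2,0·08,15,Yes
ZWE,Zimbabwe,2016,5·2,0·13,18,Yes
BFA,Burkina Faso,2017,4·6,0·15,19,Yes
STP,São Tomé and Príncipe,2014,5·7,0·00,22,No
BEN,Benin,2015,1·5,0·03,25,Yes
MLI,Mali,2015,1·5,0·05,26,Yes
MRT,Mauritania,2015,1·8,0·01,32,Yes
ZMB,Zambia,2013,3·4,0·07,32,Yes
CMR,Cameroon,2016,1·5,0·05,36,Yes
ETH,Ethiopia,2016,2·1,0·31,38,Yes
KGZ,Kyrgyzstan,2014,1·3,0·01,38,No
PSE,Palestine,2014,1·2,0·01,43,No
MMR,Myanmar,2016,1·1,0·10,44,Yes
GNB,Guinea-Bissau,2014,0·5,0·00,45,No
TGO,Togo,2016,0·3,0·00,45,Yes
AFG,Afghanistan,2016,0·3,0·02,47,Yes
PHL,Philippines,2013,0·3,0·05,47,Yes
GHA,Ghana,2016,0·2,0·01,49,Yes
UGA,Uganda,2016,0·1,0·01,49,Yes
SDN,Sudan,2014,0·0,0·00,50,No
NGA,Nigeria,2017,−0·2,−0·05,51,Yes
NPL,Nepal,2015,−0·4,−0·02,53,Yes
PAK,Pakistan,2016,−0·1,−0·02,53,No
NER,Niger,2016,−0·4,−0·01,54,Yes
CIV,Côte d'Ivoire,2016,−0·6,−0·02,56,Yes
TZA,Tanzania,2016,−1·4,−0·11,57,Yes
KHM,Cambodia,2014,−1·2,−0·03,58,No
IND,India,2016,−1·5,−3·69,58,Yes
YEM,Yemen,2013,−1·7,−0·07,58,No
BGD,Bangladesh,2014,−1·0,−0·37,59,Yes
VNM,Vietnam,2014,−0·7,−0·12,60,Yes
MNG,Mongolia,2013,−1·9,−0·01,63,No
RWA,Rwanda,2016,−2·3,−0·03,63,Yes
TLS,Timor-Leste,2016,−2·9,0·00,67,No
COG,Congo (Brazzaville),2014,−2·0,−0·01,68,No
EGY,Egypt,2014,−4·0,−0·64,72,No
COD,Democratic Republic of the Congo,2013,−1·6,−0·19,74,Yes
IDN,Indonesia,2015,−3·2,−1·59,74,Yes
BDI,Burundi,2016,−9·5,−0·15,96,Yes
GMB,Gambia,2013,−6·2,−0·02,97,No
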