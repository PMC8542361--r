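alias	canonical
USA	United States
U.S.A.	United States
U.S.	United States
US	United States
United States of America	United States
UNITED STATES	United States
America	United States
UK	United Kingdom
U.K.	United Kingdom
Great Britain	United Kingdom
Britain	United Kingdom
England	United Kingdom
Scotland	United Kingdom
Wales	United Kingdom
Northern Ireland	United Kingdom
Peoples Rep. of China	China
People's Republic of China	China
Peoples Republic of China	China
P.R. China	China
PR China	China
P. R. China	China
Mainland China	China
Republic of China	Taiwan
Republic of Korea	South Korea
Korea	South Korea
S. Korea	South Korea
Korea, Republic of	South Korea
DPR Korea	North Korea
Democratic People's Republic of Korea	North Korea
Russian Federation	Russia
The Netherlands	Netherlands
Holland	Netherlands
Czechia	Czech Republic
Czechoslovakia	Czech Republic
Slovak Republic	Slovakia
Deutschland	Germany
Federal Republic of Germany	Germany
Islamic Republic of Iran	Iran
Iran (Islamic Republic of)	Iran
Viet Nam	Vietnam
Lao PDR	Laos
Lao People's Democratic Republic	Laos
Brasil	Brazil
Espana	Spain
España	Spain
Italia	Italy
Turkiye	Turkey
Türkiye	Turkey
UAE	United Arab Emirates
Kingdom of Saudi Arabia	Saudi Arabia
KSA	Saudi Arabia
Syrian Arab Republic	Syria
Republic of Ireland	Ireland
Cote d'Ivoire	Ivory Coast
Côte d'Ivoire	Ivory Coast
Burma	Myanmar
Swaziland	Eswatini
Macedonia	North Macedonia
DR Congo	Democratic Republic of the Congo
Congo, Democratic Republic	Democratic Republic of the Congo
Congo	Republic of the Congo
Cabo Verde	Cape Verde
East Timor	Timor-Leste
Moldova, Republic of	Moldova
Republic of Moldova	Moldova
Tanzania, United Republic of	Tanzania
United Republic of Tanzania	Tanzania
Bolivia (Plurinational State of)	Bolivia
Venezuela (Bolivarian Republic of)	Venezuela
New Guinea	Papua New Guinea
Hong Kong SAR	Hong Kong
Hong Kong Special Administrative Region	Hong Kong
Macao	Macau
Taiwan, Province of China	Taiwan
ROC	Taiwan
Philippine	Philippines
The Gambia	Gambia
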