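name	codepoint
aacute	00E1
Aacute	00C1
acirc	00E2
Acirc	00C2
acute	00B4
aelig	00E6
AElig	00C6
agrave	00E0
Agrave	00C0
alefsym	2135
alpha	03B1
Alpha	0391
amp	0026
and	2227
ang	2220
apos	0027
aring	00E5
Aring	00C5
asymp	2248
atilde	00E3
Atilde	00C3
auml	00E4
Auml	00C4
bdquo	201E
beta	03B2
Beta	0392
brvbar	00A6
bull	2022
cap	2229
ccedil	00E7
Ccedil	00C7
cedil	00B8
cent	00A2
chi	03C7
Chi	03A7
circ	02C6
clubs	2663
cong	2245
copy	00A9
crarr	21B5
cup	222A
curren	00A4
dagger	2020
Dagger	2021
darr	2193
dArr	21D3
deg	00B0
delta	03B4
Delta	0394
diams	2666
divide	00F7
eacute	00E9
Eacute	00C9
ecirc	00EA
Ecirc	00CA
egrave	00E8
Egrave	00C8
empty	2205
emsp	2003
ensp	2002
epsilon	03B5
Epsilon	0395
equiv	2261
eta	03B7
Eta	0397
eth	00F0
ETH	00D0
euml	00EB
Euml	00CB
euro	20AC
exist	2203
fnof	0192
forall	2200
frac12	00BD
frac14	00BC
frac34	00BE
frasl	2044
gamma	03B3
Gamma	0393
ge	2265
gt	003E
harr	2194
hArr	21D4
hearts	2665
hellip	2026
horbar	2015
iacute	00ED
Iacute	00CD
icirc	00EE
Icirc	00CE
iexcl	00A1
igrave	00EC
Igrave	00CC
infin	221E
int	222B
iota	03B9
Iota	0399
iquest	00BF
isin	2208
iuml	00EF
Iuml	00CF
kappa	03BA
Kappa	039A
lambda	03BB
Lambda	039B
lang	2329
laquo	00AB
larr	2190
lArr	21D0
lceil	2308
ldquo	201C
le	2264
lfloor	230A
lowast	2217
loz	25CA
lrm	200E
lsaquo	2039
lsquo	2018
lt	003C
macr	00AF
mdash	2014
micro	00B5
middot	00B7
minus	2212
mu	03BC
Mu	039C
nabla	2207
nbsp	00A0
ndash	2013
ne	2260
ni	220B
not	00AC
notin	2209
nsub	2284
ntilde	00F1
Ntilde	00D1
nu	03BD
Nu	039D
oacute	00F3
Oacute	00D3
ocirc	00F4
Ocirc	00D4
oelig	0153
OElig	0152
ograve	00F2
Ograve	00D2
oline	203E
omega	03C9
Omega	03A9
omicron	03BF
Omicron	039F
oplus	2295
or	2228
ordf	00AA
ordm	00BA
oslash	00F8
Oslash	00D8
otilde	00F5
Otilde	00D5
otimes	2297
ouml	00F6
Ouml	00D6
para	00B6
part	2202
permil	2030
perp	22A5
phi	03C6
Phi	03A6
pi	03C0
Pi	03A0
piv	03D6
plusmn	00B1
pound	00A3
prime	2032
Prime	2033
prod	220F
prop	221D
psi	03C8
Psi	03A8
quot	0022
radic	221A
rang	232A
raquo	00BB
rarr	2192
rArr	21D2
rceil	2309
rdquo	201D
reg	00AE
rfloor	230B
rho	03C1
Rho	03A1
rlm	200F
rsaquo	203A
rsquo	2019
sbquo	201A
scaron	0161
Scaron	0160
sdot	22C5
sect	00A7
shy	00AD
sigma	03C3
Sigma	03A3
sigmaf	03C2
sim	223C
spades	2660
sub	2282
sube	2286
sum	2211
sup	2283
sup1	00B9
sup2	00B2
sup3	00B3
supe	2287
szlig	00DF
tau	03C4
Tau	03A4
there4	2234
theta	03B8
Theta	0398
thetasym	03D1
thinsp	2009
thorn	00FE
THORN	00DE
tilde	02DC
times	00D7
trade	2122
uacute	00FA
Uacute	00DA
uarr	2191
uArr	21D1
ucirc	00FB
Ucirc	00DB
ugrave	00F9
Ugrave	00D9
uml	00A8
upsih	03D2
upsilon	03C5
Upsilon	03A5
uuml	00FC
Uuml	00DC
xi	03BE
Xi	039E
yacute	00FD
Yacute	00DD
yen	00A5
yuml	00FF
Yuml	0178
zeta	03B6
Zeta	0396
zwj	200D
zwnj	200C
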