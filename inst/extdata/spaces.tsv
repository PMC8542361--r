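codepoint
0009
00A0
1680
2000
2001
2002
2003
2004
2005
2006
2007
2008
2009
200A
200B
202F
205F
2060
3000
FEFF
180E
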