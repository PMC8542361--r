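codepoint
00AD
2010
2011
2012
2013
2014
2015
2212
FE58
FE63
FF0D
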