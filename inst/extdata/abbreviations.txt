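al
approx
ca
cf
cp
Dr
Drs
e.g
Ed
Eds
etc
et al
Fig
Figs
i.e
Inc
Jr
Ltd
M.D
Mr
Mrs
Ms
No
Nos
Ph.D
Prof
resp
Sr
St
Tab
Tabs
v
viz
vol
vs
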