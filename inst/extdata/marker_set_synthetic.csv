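marker_id
dnaA
dnaN
gyrA
gyrB
recA
rpoA
rpoB
rpoC
rpsB
rpsC
rpsE
rpsK
rplB
rplC
rplD
rplE
rplF
rplM
rplN
rplP
infB
infC
tsf
fusA
tufA
secY
ffh
pheS
pheT
ileS
leuS
valS
alaS
argS
serS
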