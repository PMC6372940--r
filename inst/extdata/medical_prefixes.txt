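amni
angi
arteri
arthr
bronch
cardi
cephal
cerebr
chondr
cyst
cyt
derm
encephal
enter
gastr
gluc
glyc
haem
hemat
hemo
hepat
hyper
hypo
immun
laryng
leuk
lymph
mening
myel
nephr
neur
onc
ophthalm
oste
path
pharmac
phleb
pneum
psych
pulmon
ren
rhin
thromb
thyro
tox
vascul
ven
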