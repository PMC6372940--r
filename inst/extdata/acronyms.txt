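adhd
aids
bmi
bp
copd
cpr
ct
dna
ecg
ekg
er
gerd
hdl
hiv
ibs
icu
ldl
mri
ms
nsaid
ocd
pcr
ptsd
rna
tb
tia
uti
who
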