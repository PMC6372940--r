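algia
cele
centesis
cyte
ectasis
ectomy
emia
genesis
gram
graphy
itis
lysis
malacia
megaly
meter
oma
opathy
osis
ostomy
otomy
pathy
penia
pepsia
phagia
phasia
philia
phobia
plasia
plasty
plegia
pnea
ptosis
rrhage
rrhea
sclerosis
scopy
stenosis
therapy
tension
trophy
uria
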