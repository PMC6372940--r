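abdomen
acute
allergy
antibiotic
antibody
artery
benign
biopsy
cardiac
cartilage
chronic
clinical
diagnosis
dosage
embolus
enzyme
fracture
gland
hemoglobin
hormone
immune
incision
infection
inflammation
intravenous
lesion
ligament
malignant
membrane
metabolism
mucus
nerve
oral
palliative
pathogen
plasma
prognosis
pulmonary
renal
respiratory
saline
spasm
suture
symptom
syndrome
systolic
tendon
tissue
tumor
vaccine
vein
ventricle
virus
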