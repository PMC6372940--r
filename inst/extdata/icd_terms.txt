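anemia
angina
appendicitis
arthritis
asthma
bronchitis
cancer
cataract
cirrhosis
colitis
dementia
depression
dermatitis
diabetes
eczema
embolism
emphysema
epilepsy
fibrosis
gastritis
glaucoma
gout
hepatitis
hernia
hypertension
influenza
insomnia
leukemia
lymphoma
malaria
measles
melanoma
meningitis
migraine
nephritis
neuropathy
obesity
osteoporosis
pancreatitis
pneumonia
psoriasis
sciatica
sepsis
shingles
sinusitis
stroke
tendinitis
thrombosis
tuberculosis
ulcer
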