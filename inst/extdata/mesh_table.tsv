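term	depth	group
pain	2	symptom
headache	4	symptom
fever	3	symptom
cough	3	symptom
nausea	4	symptom
fatigue	3	symptom
dizziness	4	symptom
vomiting	4	symptom
rash	3	symptom
chest pain	5	symptom
back pain	5	symptom
dyspnea	5	symptom
pruritus	5	symptom
syncope	6	symptom
tinnitus	6	symptom
palpitations	6	symptom
edema	4	symptom
stroke	4	disease
diabetes	3	disease
asthma	4	disease
flu	3	disease
pneumonia	4	disease
migraine	5	disease
depression	3	disease
anxiety	3	disease
arthritis	4	disease
eczema	5	disease
ulcer	4	disease
anemia	3	disease
hypertension	4	disease
heart attack	5	disease
myocardial infarction	6	disease
atrial fibrillation	7	disease
osteoporosis	5	disease
hypothyroidism	6	disease
gastroesophageal reflux	7	disease
angina pectoris	6	disease
meningitis	5	disease
tuberculosis	4	disease
leukemia	5	disease
vaccine	3	other
antibiotic	3	other
surgery	2	other
chemotherapy	4	other
biopsy	3	other
anticoagulant	5	other
blood test	4	other
x ray	3	other
physical therapy	4	other
palliative care	5	other
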