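term	score	group
headache	0.92	symptom
chest pain	0.88	symptom
sore throat	0.90	symptom
runny nose	0.91	symptom
fever	0.93	symptom
cough	0.94	symptom
dizziness	0.78	symptom
fatigue	0.75	symptom
nausea	0.72	symptom
vomiting	0.80	symptom
shortness of breath	0.70	symptom
back pain	0.89	symptom
rash	0.86	symptom
swelling	0.82	symptom
itching	0.88	symptom
palpitations	0.45	symptom
tinnitus	0.38	symptom
dyspnea	0.18	symptom
pruritus	0.12	symptom
syncope	0.20	symptom
heart attack	0.85	disease
high blood pressure	0.83	disease
stroke	0.81	disease
diabetes	0.79	disease
asthma	0.84	disease
flu	0.95	disease
cold	0.96	disease
pneumonia	0.66	disease
migraine	0.74	disease
depression	0.77	disease
anxiety	0.76	disease
arthritis	0.68	disease
eczema	0.58	disease
ulcer	0.62	disease
anemia	0.55	disease
hypertension	0.35	disease
myocardial infarction	0.15	disease
angina pectoris	0.22	disease
gastroesophageal reflux	0.17	disease
atrial fibrillation	0.21	disease
osteoporosis	0.40	disease
hypothyroidism	0.25	disease
blood test	0.87	other
x ray	0.90	other
vaccine	0.80	other
antibiotic	0.73	other
surgery	0.85	other
chemotherapy	0.60	other
biopsy	0.50	other
anticoagulant	0.20	other
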