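acetaminophen
albuterol
amlodipine
amoxicillin
aspirin
atorvastatin
azithromycin
ciprofloxacin
citalopram
clopidogrel
codeine
diazepam
doxycycline
fluoxetine
furosemide
gabapentin
hydrochlorothiazide
ibuprofen
insulin
levothyroxine
lisinopril
loratadine
losartan
metformin
metoprolol
morphine
naproxen
omeprazole
paracetamol
penicillin
prednisone
ramipril
sertraline
simvastatin
tramadol
warfarin
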