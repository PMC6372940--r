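advice
ago
almost
already
answer
anyone
anything
appointment
arm
asked
aches
ache
bit
blood
bone
breath
breathe
checked
chest
clinic
couple
days
daughter
different
dose
doses
ear
ears
eyes
feeling
felt
gave
getting
going
gone
hands
happened
having
health
hospital
hours
husband
kids
knee
knees
later
legs
lot
lots
lower
lungs
maybe
medication
medications
minutes
month
months
morning
mouth
nose
nothing
nurse
past
pill
pills
pressure
really
results
says
seeing
shot
since
skin
son
sometimes
started
stomach
sure
symptoms
taking
teeth
test
tests
thanks
things
thought
throat
times
tooth
treatment
trying
upper
visit
weeks
wife
worse
years
yesterday
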