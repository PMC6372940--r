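word	syllables
abbreviate	4
able	2
anxious	2
area	3
average	3
awful	2
beautiful	3
because	2
bottle	2
business	2
cafe	2
candle	2
cardiovascular	6
chocolate	2
circle	2
comfortable	3
create	2
decade	2
disease	2
double	2
evening	2
every	2
everyone	3
family	3
favorite	3
fine	1
fire	1
gentle	2
give	1
have	1
hour	1
house	1
idea	3
include	2
interesting	3
juice	1
life	1
like	1
little	2
live	1
love	1
made	1
make	1
medicine	3
middle	2
minute	2
more	1
move	1
muscle	2
name	1
nausea	3
needle	2
nurse	1
once	1
people	2
physiotherapy	6
piece	1
please	1
purple	2
quiet	2
science	2
simple	2
some	1
something	2
sore	1
table	2
take	1
time	1
tissue	2
trouble	2
twice	1
ulcer	2
understandability	7
use	1
usual	3
vaccine	2
voice	1
wave	1
where	1
while	1
whole	1
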