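word	polarity
good	pos
great	pos
happy	pos
hope	pos
hopeful	pos
love	pos
better	pos
best	pos
relief	pos
relieved	pos
glad	pos
thankful	pos
thanks	pos
helpful	pos
amazing	pos
wonderful	pos
fine	pos
safe	pos
calm	pos
improved	pos
improving	pos
comfortable	pos
easy	pos
healthy	pos
strong	pos
bad	neg
worse	neg
worst	neg
scared	neg
scary	neg
afraid	neg
worried	neg
worry	neg
terrible	neg
awful	neg
horrible	neg
painful	neg
hurt	neg
hurts	neg
sad	neg
angry	neg
upset	neg
panic	neg
fear	neg
miserable	neg
exhausted	neg
weak	neg
sick	neg
dying	neg
hopeless	neg
anxious	neg
stressed	neg
crying	neg
suffering	neg
unbearable	neg
normal	neu
usual	neu
common	neu
typical	neu
standard	neu
regular	neu
average	neu
moderate	neu
routine	neu
general	neu
stable	neu
steady	neu
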