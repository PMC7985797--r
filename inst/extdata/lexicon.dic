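%
1	posemo
2	negemo
3	insight
4	achieve
5	social
%
good	1
great	1
happi*	1
love*	1
nice	1
fun	1
joy*	1
excit*	1
awesome	1
glad	1
smile*	1
laugh*	1
sad	2
bad	2
hate*	2
angry	2
anger	2
fear*	2
worri*	2
terrible	2
awful	2
cry*	2
hurt*	2
lonely	2
think*	3
know*	3
wonder*	3
realize*	3
idea*	3
curious	3
imagine*	3
learn*	3
question*	3
reason*	3
insight*	3
work*	4
plan*	4
goal*	4
finish*	4
achieve*	4
effort*	4
succeed*	4
success*	4
complete*	4
task*	4
earn*	4
friend*	5
family	5
together	5
share*	5
talk*	5
team*	5
neighbor*	5
community	5
help*	5
visit*	5
parti*	5
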