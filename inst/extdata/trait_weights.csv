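trait,category,weight
openness,_intercept,0
openness,insight,10
openness,achieve,1
conscientiousness,_intercept,0
conscientiousness,achieve,10
conscientiousness,insight,1
extraversion,_intercept,0
extraversion,posemo,10
extraversion,social,1.5
agreeableness,_intercept,0
agreeableness,social,10
agreeableness,posemo,1.5
neuroticism,_intercept,0
neuroticism,negemo,10
neuroticism,posemo,-1.5
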