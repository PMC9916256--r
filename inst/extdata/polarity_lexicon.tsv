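token	score
toxicity	-0.9
toxic	-0.85
bleeding	-0.8
hemorrhage	-0.85
fatal	-1.0
death	-0.95
arrhythmia	-0.75
seizure	-0.8
overdose	-0.85
dangerous	-0.9
severe	-0.7
serious	-0.65
adverse	-0.6
risk	-0.5
inhibit	-0.35
inhibits	-0.35
reduce	-0.5
reduces	-0.5
decrease	-0.4
decreases	-0.4
impair	-0.55
impairs	-0.55
worsen	-0.7
worsens	-0.7
prolong	-0.45
prolongs	-0.45
accumulate	-0.4
accumulation	-0.4
contraindicated	-0.9
caution	-0.45
avoid	-0.6
harm	-0.75
harmful	-0.8
nephrotoxicity	-0.85
hepatotoxicity	-0.85
hypotension	-0.6
hypertension	-0.6
sedation	-0.35
dizziness	-0.4
nausea	-0.35
improve	0.7
improves	0.7
improved	0.7
benefit	0.75
beneficial	0.8
enhance	0.45
enhances	0.45
synergistic	0.5
synergy	0.5
effective	0.6
efficacy	0.55
safe	0.8
safely	0.8
tolerated	0.6
augment	0.35
augments	0.35
potentiate	0.2
protective	0.7
advantageous	0.85
favorable	0.7
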