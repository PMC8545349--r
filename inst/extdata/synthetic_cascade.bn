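# Synthetic demonstration model, constructed for this package (not a
# published network): two external inputs feed a signalling cascade through a
# highly connected core regulator with a negative feedback loop.
targets, factors
IN1, IN1
IN2, IN2
SIG, IN1 & !FBK
GATE, SIG | IN2
HUB, GATE & !FBK
TF1, HUB
TF2, HUB & GATE
TF3, HUB | TF1
TF4, !HUB
EFF1, TF1 & TF2
EFF2, TF3 & !TF4
FBK, EFF1 | EFF2
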