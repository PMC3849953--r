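condition,category,symbol,is_reference
Condition I,Virtual,EV0,TRUE
Condition I,Embedded,EV1,FALSE
Condition II,Return,RR0,TRUE
Condition II,Reach,RR1,FALSE
Condition III,Against Gravity,G0,TRUE
Condition III,Towards Gravity,G1,FALSE
Condition III,Ground Level,G2,FALSE
Condition IV,Large cross-body component,CB0,TRUE
Condition IV,Small cross-body component,CB1,FALSE
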