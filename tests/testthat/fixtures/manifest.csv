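report_id,patient_id,cohort
r1,P1,MUTANT
r2,P1,MUTANT
r3,P2,WILDTYPE
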