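sex,age_months,L,M,S
male,192,-1.6,20.0,0.12
male,204,-1.7,20.5,0.12
female,192,-1.5,20.6,0.13
female,204,-1.6,21.0,0.13
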