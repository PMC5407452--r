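stage	age_dpc
CS17	42
CS18	45
CS19	48
CS20	50
CS21	52
CS22	54
CS23	56.5
F1	60
F2	66
F3	73
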