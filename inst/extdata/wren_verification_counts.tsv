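species	class	n_verified	n_correct
Moustached Wren	0.1-0.3	100	60
Moustached Wren	0.3-0.5	100	66
Moustached Wren	0.5-0.7	100	87
Moustached Wren	>0.7	150	113
Buff-breasted Wren	0.1-0.3	100	42
Buff-breasted Wren	0.3-0.5	100	66
Buff-breasted Wren	0.5-0.7	100	87
Buff-breasted Wren	>0.7	150	149
Thrush-like Wren	0.1-0.3	100	47
Thrush-like Wren	0.3-0.5	100	85
Thrush-like Wren	0.5-0.7	100	98
Thrush-like Wren	>0.7	150	148
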