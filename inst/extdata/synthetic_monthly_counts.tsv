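species	cell	ST01	ST02	ST03	ST04	ST05
Thrush-like Wren	Jun	334	294	267	240	200
Thrush-like Wren	Jul	225	198	180	162	135
Thrush-like Wren	Aug	213	187	170	153	127
Thrush-like Wren	Sep	220	194	176	158	132
Thrush-like Wren	Oct	238	209	190	171	142
Thrush-like Wren	Nov	250	220	200	180	150
Thrush-like Wren	Dec	303	266	242	218	182
Thrush-like Wren	Jan	247	217	197	177	148
Thrush-like Wren	Feb	225	198	180	162	135
Thrush-like Wren	Mar	375	330	300	270	225
Thrush-like Wren	Apr	400	352	320	288	240
Thrush-like Wren	May	375	330	300	270	225
Buff-breasted Wren	Jun	12	11	10	9	7
Buff-breasted Wren	Jul	6	6	5	4	4
Buff-breasted Wren	Aug	6	5	4	4	3
Buff-breasted Wren	Sep	6	6	5	4	4
Buff-breasted Wren	Oct	8	7	6	5	4
Buff-breasted Wren	Nov	9	8	7	6	5
Buff-breasted Wren	Dec	15	13	12	10	9
Buff-breasted Wren	Jan	9	8	8	7	6
Buff-breasted Wren	Feb	8	7	6	5	5
Buff-breasted Wren	Mar	14	12	11	10	8
Buff-breasted Wren	Apr	16	14	12	11	9
Buff-breasted Wren	May	15	13	12	11	9
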