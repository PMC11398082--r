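species	cell	ST01	ST02	ST03	ST04	ST05
Thrush-like Wren	00	6	6	5	4	4
Thrush-like Wren	01	5	4	4	4	3
Thrush-like Wren	02	5	4	4	4	3
Thrush-like Wren	03	8	7	6	5	4
Thrush-like Wren	04	22	19	17	16	13
Thrush-like Wren	05	100	88	80	72	60
Thrush-like Wren	06	725	638	580	522	435
Thrush-like Wren	07	600	528	480	432	360
Thrush-like Wren	08	475	418	380	342	285
Thrush-like Wren	09	150	132	120	108	90
Thrush-like Wren	10	125	110	100	90	75
Thrush-like Wren	11	100	88	80	72	60
Thrush-like Wren	12	88	77	70	63	52
Thrush-like Wren	13	83	73	66	59	49
Thrush-like Wren	14	88	77	70	63	52
Thrush-like Wren	15	100	88	80	72	60
Thrush-like Wren	16	125	110	100	90	75
Thrush-like Wren	17	200	176	160	144	120
Thrush-like Wren	18	225	198	180	162	135
Thrush-like Wren	19	100	88	80	72	60
Thrush-like Wren	20	38	33	30	27	22
Thrush-like Wren	21	20	18	16	14	12
Thrush-like Wren	22	10	9	8	7	6
Thrush-like Wren	23	8	7	6	5	4
Buff-breasted Wren	00	1	0	0	0	0
Buff-breasted Wren	01	1	0	0	0	0
Buff-breasted Wren	02	1	0	0	0	0
Buff-breasted Wren	03	1	1	0	0	0
Buff-breasted Wren	04	1	1	1	1	1
Buff-breasted Wren	05	6	6	5	4	4
Buff-breasted Wren	06	28	24	22	20	16
Buff-breasted Wren	07	23	20	18	16	13
Buff-breasted Wren	08	15	13	12	11	9
Buff-breasted Wren	09	5	4	4	4	3
Buff-breasted Wren	10	4	3	3	3	2
Buff-breasted Wren	11	3	2	2	2	1
Buff-breasted Wren	12	2	2	2	1	1
Buff-breasted Wren	13	2	2	2	1	1
Buff-breasted Wren	14	3	2	2	2	1
Buff-breasted Wren	15	3	3	2	2	2
Buff-breasted Wren	16	4	4	4	3	3
Buff-breasted Wren	17	8	7	6	5	4
Buff-breasted Wren	18	9	8	7	6	5
Buff-breasted Wren	19	4	3	3	3	2
Buff-breasted Wren	20	2	2	2	1	1
Buff-breasted Wren	21	1	1	1	1	0
Buff-breasted Wren	22	1	1	0	0	0
Buff-breasted Wren	23	1	0	0	0	0
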