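pattern	label	priority	compound
homodimer of	2	1	TRUE
homotrimer of	3	2	TRUE
homotetramer of	4	3	TRUE
homopentamer of	5	4	TRUE
homohexamer of	6	5	TRUE
homoheptamer of	7	6	TRUE
homooctamer of	8	7	TRUE
homodecamer of	10	8	TRUE
homododecamer of	12	9	TRUE
monomer	1	10	FALSE
homodimer	2	11	FALSE
homotrimer	3	12	FALSE
homotetramer	4	13	FALSE
homopentamer	5	14	FALSE
homohexamer	6	15	FALSE
homoheptamer	7	16	FALSE
homooctamer	8	17	FALSE
homodecamer	10	18	FALSE
homododecamer	12	19	FALSE
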