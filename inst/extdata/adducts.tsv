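name	delta_C	delta_H	charge	source_solvent
[M-H]+	0	-1	1	any
[M+H]+	0	1	1	toluene
[M]+.	0	0	1	toluene
[M+C3H3]+	3	3	1	hexane
[M+C4H9]+	4	9	1	isooctane
[M+C6H13]+	6	13	1	hexane
[M+C7H9]+	7	9	1	toluene
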