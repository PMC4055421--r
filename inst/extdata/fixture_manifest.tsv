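res_i	res_j	n_ij	excluded	I_ij	edge
1	2	9	TRUE	14.4300144300144	FALSE
1	3	3	FALSE	4.81000481000481	TRUE
2	3	9	TRUE	14.4300144300144	FALSE
3	5	1	FALSE	1.69570673628676	FALSE
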