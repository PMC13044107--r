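gene	allele	function_class	activity_value
CYP2D6	*1	normal	1.0
CYP2D6	*2	normal	1.0
CYP2D6	*10	decreased	0.25
CYP2D6	*41	decreased	0.5
CYP2D6	*5	no_function	0.0
CYP2D6	*14	no_function	0.0
CYP2D6	*4	no_function	0.0
CYP2D6	*22	uncertain	NA
CYP2C19	*1	normal	NA
CYP2C19	*17	increased	NA
CYP2C19	*2	no_function	NA
CYP2C19	*3	no_function	NA
CYP2C19	*9	decreased	NA
CYP2C19	*12	uncertain	NA
CYP2B6	*1	normal	NA
CYP2B6	*4	increased	NA
CYP2B6	*22	increased	NA
CYP2B6	*6	decreased	NA
CYP2B6	*9	decreased	NA
CYP2B6	*18	no_function	NA
CYP2B6	*28	unknown	NA
SLCO1B1	*1	normal	NA
SLCO1B1	*37	normal	NA
SLCO1B1	*14	increased	NA
SLCO1B1	*5	decreased	NA
SLCO1B1	*15	decreased	NA
SLCO1B1	*31	uncertain	NA
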