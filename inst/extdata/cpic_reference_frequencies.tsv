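population	context	category	frequency	n	note
east_asian	codeine_tramadol	Use as directed	0.532	21185
east_asian	codeine_tramadol	Use with caution	0.385	21185
east_asian	codeine_tramadol	Not determined	0.067	21185
east_asian	codeine_tramadol	Avoid and/or use alternative medication	0.015	21185
east_asian	lova_pita_simva	Use as directed	0.757	2471
east_asian	lova_pita_simva	Avoid and/or use alternative medication	0.235	2471
east_asian	lova_pita_simva	Not determined	0.008	2471
east_asian	pravastatin	Use as directed	0.757	2471
east_asian	pravastatin	Use with caution	0.219	2471	also printed as 22.0% in one source table
east_asian	pravastatin	Avoid and/or use alternative medication	0.016	2471
east_asian	pravastatin	Not determined	0.008	2471
east_asian	atorvastatin	Use as directed	0.757	2471
east_asian	atorvastatin	Adjust dosage	0.219	2471	also printed as 22.0% in one source table
east_asian	atorvastatin	Avoid and/or use alternative medication	0.016	2471
east_asian	atorvastatin	Not determined	0.008	2471
east_asian	sertraline	Adjust dosage	0.528	32510
east_asian	sertraline	Use as directed	0.322	32510
east_asian	sertraline	Avoid and/or use alternative medication	0.150	32510
east_asian	sertraline	Not determined	0.000	32510
east_asian	citalopram_escitalopram	Adjust dosage	0.460	32510
east_asian	citalopram_escitalopram	Use as directed	0.381	32510
east_asian	citalopram_escitalopram	Avoid and/or use alternative medication	0.156	32510
east_asian	citalopram_escitalopram	Not determined	0.003	32510
japanese_cohort	codeine_tramadol	Use as directed	0.710	632
japanese_cohort	codeine_tramadol	Use with caution	0.250	632	source table prints 0.9% but its CI (23.4%-30.3%) and the comparison table print 25.0%; 25.0% carried here
japanese_cohort	codeine_tramadol	Not determined	0.030	632
japanese_cohort	codeine_tramadol	Avoid and/or use alternative medication	0.009	632
japanese_cohort	lova_pita_simva	Use as directed	0.676	632
japanese_cohort	lova_pita_simva	Avoid and/or use alternative medication	0.275	632
japanese_cohort	lova_pita_simva	Not determined	0.049	632
japanese_cohort	pravastatin	Use as directed	0.676	632
japanese_cohort	pravastatin	Use with caution	0.258	632
japanese_cohort	pravastatin	Avoid and/or use alternative medication	0.017	632
japanese_cohort	pravastatin	Not determined	0.049	632
japanese_cohort	atorvastatin	Use as directed	0.676	632
japanese_cohort	atorvastatin	Adjust dosage	0.258	632
japanese_cohort	atorvastatin	Avoid and/or use alternative medication	0.017	632
japanese_cohort	atorvastatin	Not determined	0.049	632
japanese_cohort	sertraline	Adjust dosage	0.508	632
japanese_cohort	sertraline	Use as directed	0.316	632
japanese_cohort	sertraline	Avoid and/or use alternative medication	0.176	632
japanese_cohort	sertraline	Not determined	0.000	632
japanese_cohort	citalopram_escitalopram	Adjust dosage	0.461	631
japanese_cohort	citalopram_escitalopram	Use as directed	0.361	631
japanese_cohort	citalopram_escitalopram	Avoid and/or use alternative medication	0.177	631
japanese_cohort	citalopram_escitalopram	Not determined	0.000	631
japanese_external	codeine_tramadol	Use as directed	0.742	216	independent Japanese genotyping study (six CYP2D6 alleles, female cohort)
japanese_external	codeine_tramadol	Use with caution	0.241	216	independent Japanese genotyping study (six CYP2D6 alleles, female cohort)
japanese_external	codeine_tramadol	Avoid and/or use alternative medication	0.019	216	independent Japanese genotyping study (six CYP2D6 alleles, female cohort)
japanese_external	codeine_tramadol	Not determined	0.000	216	independent Japanese genotyping study (six CYP2D6 alleles, female cohort)
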