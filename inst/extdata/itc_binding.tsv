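# Published ITC binding measurements for murine alpha-E-catenin variants and
# complexes at 25 C. kd in molar, energies in kcal/mol; tds_printed and
# dg_printed are the one-decimal values as printed alongside the
# measurements. NA = no binding detected.
cell	titrant	kd	kd_sd	dh	dh_sd	tds_printed	dg_printed
alphaE-catenin R551A	Vinculin D1	4.1e-9	2.2e-9	7.7	1.0	19.0	-11.4
alphaE-catenin R551A.beta-catenin.Ecyto	Vinculin D1	2.6e-8	1.4e-8	6.7	0.5	17.0	-10.3
alphaE-catenin R551A	Vinculin Full Length	NA	NA	NA	NA	NA	NA
alphaE-catenin R551A	beta-catenin	7.8e-8	1.7e-8	-33.3	1.8	-23.6	-9.7
alphaE-catenin R551A	beta-catenin.Ecyto	1.4e-8	0.6e-8	-32.3	2.4	-21.6	-10.7
alphaE-catenin wt	Vinculin D1	1.8e-6	0.2e-6	12.6	0.6	20.4	-7.8
alphaE-catenin MI-MII	Vinculin D1	5.2e-9	0.3e-9	9.9	0.1	21.2	-11.3
alphaE-catenin.beta-catenin.Ecyto	Vinculin D1	1.9e-6	0.4e-6	1.4	0.1	9.2	-7.8
alphaE-catenin wt	Vinculin Full Length	NA	NA	NA	NA	NA	NA
alphaE-catenin wt	beta-catenin	2.3e-8	0.4e-8	-16.1	0.7	-5.7	-10.4
alphaE-catenin wt	beta-catenin.Ecyto	0.9e-9	0.3e-9	-10.1	0.1	2.2	-12.3
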