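# Standard Gibbs free energies of formation at 298.15 K (aqueous species at
# unit activity, solids/liquids pure phase), assembled from standard
# physical-chemistry compilations (CRC Handbook style values, kJ/mol).
# Element columns give the atomic composition used for balance checks.
species	charge	phase	dGf0_kJ_mol	Fe	N	O	H
H+	1	aqueous	0.0	0	0	0	1
OH-	-1	aqueous	-157.24	0	0	1	1
H2O	0	liquid	-237.13	0	0	1	2
Fe2+	2	aqueous	-78.90	1	0	0	0
Fe3+	3	aqueous	-4.70	1	0	0	0
NO3-	-1	aqueous	-108.74	0	1	3	0
NO2-	-1	aqueous	-32.20	0	1	2	0
NH4+	1	aqueous	-79.31	0	1	0	4
N2	0	gas	0.0	0	2	0	0
O2	0	gas	0.0	0	0	2	0
Fe(OH)3	0	solid	-696.50	1	0	3	3
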