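# Reconstruction of the 13 metagenome-assembled genomes (MAGs) recovered from
# the pilot-scale groundwater filter enrichment: taxonomy, long-read relative
# abundance (%), CheckM-style completeness/contamination (%), full-length
# rRNA presence and tRNA counts. rRNA/tRNA fields are a reconstruction chosen
# to be consistent with the published MIMAG quality tier of each genome
# (MAG.29 passes the completeness/contamination cut but was reported Medium,
# so its 16S is marked not full-length here); they are not raw data.
mag_id	taxonomy	phylum	relative_abundance	completeness	contamination	rrna_5s	rrna_16s	rrna_23s	trna_count
MAG.13	Candidatus Siderophilus nitratireducens	Proteobacteria	19.3	98.59	1.73	TRUE	TRUE	TRUE	20
MAG.26	f__Gallionellaceae	Proteobacteria	10.0	95.81	0.95	TRUE	TRUE	TRUE	20
MAG.18	f__Anaeromyxobacteraceae	Proteobacteria	8.6	98.06	0.65	TRUE	TRUE	TRUE	21
MAG.19	g__Devosia	Proteobacteria	6.5	99.28	0.14	TRUE	TRUE	TRUE	20
MAG.10	f__Chitinophagaceae	Bacteroidetes	5.6	97.54	0.90	TRUE	TRUE	TRUE	19
MAG.03	o__Nanopelagicales	Actinobacteria	4.3	99.00	2.37	TRUE	TRUE	TRUE	20
MAG.27	o__Nanopelagicales	Actinobacteria	3.9	98.30	1.98	TRUE	TRUE	TRUE	19
MAG.34	g__Gallionella	Proteobacteria	3.5	95.91	3.25	TRUE	TRUE	TRUE	18
MAG.00	o__Anaerolineales	Chloroflexi	1.4	97.27	2.91	TRUE	TRUE	TRUE	20
MAG.08	g__Rhodoferax	Proteobacteria	1.2	88.95	2.37	TRUE	TRUE	TRUE	20
MAG.04	f__Rhizobiaceae	Proteobacteria	0.9	95.12	4.10	TRUE	TRUE	TRUE	19
MAG.16	f__Gallionellaceae	Proteobacteria	0.9	88.51	3.94	TRUE	TRUE	TRUE	18
MAG.29	g__Rhizobacter	Proteobacteria	0.7	94.54	4.54	TRUE	FALSE	TRUE	19
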