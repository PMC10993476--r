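# Influent and effluent water characteristics of the pilot-scale groundwater
# filter during the nitrate-limited steady state (days 21-77): daily-mean and
# standard deviation per stream, detection limits and censoring flags.
# Concentrations in umol/L except DOC (mg/L); dissolved Fe3+ is the
# solubility-equilibrium estimate, not a measurement.
species	units	influent_mean	influent_sd	influent_below_detection	effluent_mean	effluent_sd	effluent_below_detection	detection_limit
NO3-	umol/L	8.1	2.1	FALSE	1	NA	TRUE	1
NO2-	umol/L	0.2	NA	TRUE	0.2	NA	TRUE	0.2
Fe2+	umol/L	236	4	FALSE	178	5	FALSE	0.18
O2	umol/L	3	NA	TRUE	3	NA	TRUE	3
NH4+	umol/L	11	1.0	FALSE	11	8.1	FALSE	0.1
DOC	mg/L	3.1	0.1	FALSE	2.0	0.2	FALSE	0.1
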