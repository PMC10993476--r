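# Per-MAG marker-gene reconstruction for the pilot-filter community. Each
# MAG's set encodes its published capability calls (iron oxidation,
# denitrification step range, carbon fixation) as explicit markers so that
# the rule engine, not a lookup table, reproduces the calls. A reported step
# range such as "NO3 -> NO" is expanded into markers for every step it spans
# (here napAB or narGHI plus nirK or nirS); "NO -> N2" is encoded as
# norBC + nosZ (interpretation: the range spans both reductions).
mag_id	gene
MAG.13	cyc2
MAG.13	K02567
MAG.13	K02568
MAG.13	K01601
MAG.13	K00855
MAG.26	cyc2
MAG.26	K02567
MAG.26	K02568
MAG.26	K00368
MAG.26	K00376
MAG.26	K01601
MAG.26	K00855
MAG.18	K00376
MAG.19	K00368
MAG.10	K04561
MAG.10	K02305
MAG.10	K00376
MAG.03	K00370
MAG.03	K00371
MAG.03	K00374
MAG.03	K15864
MAG.27	K02567
MAG.27	K02568
MAG.27	K00368
MAG.34	cyc2
MAG.34	cyc1
MAG.34	K02567
MAG.34	K02568
MAG.34	K15864
MAG.34	K01602
MAG.34	K00855
MAG.00	K15864
MAG.08	K02567
MAG.08	K02568
MAG.08	K00368
MAG.08	K01601
MAG.08	K00855
MAG.04	K02567
MAG.04	K02568
MAG.04	K00368
MAG.04	K04561
MAG.04	K02305
MAG.16	cyc2
MAG.16	K00370
MAG.16	K00371
MAG.16	K00374
MAG.16	K00368
MAG.16	K04561
MAG.16	K02305
MAG.16	K01601
MAG.16	K00855
MAG.29	cyc2
MAG.29	K02567
MAG.29	K02568
MAG.29	K01601
MAG.29	K00855
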