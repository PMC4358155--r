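# Synthetic stand-in transition matrix (U) for an 8-stage Calathea
# ovandensis-style understory herb.  Constructed from plausible vital
# rates; NOT the published field-estimated matrix.
# Stages: seed bank, seedling, juvenile, pre-reproductive, small,
# medium, large, extra-large reproductives.  Columns = source stage.
seed,seedling,juvenile,prerepro,small,medium,large,xlarge
0.35,0,0,0,0,0,0,0
0.05,0.05,0.02,0,0,0,0,0
0,0.30,0.20,0.05,0,0,0,0
0,0.03,0.45,0.30,0.10,0,0,0
0,0,0.10,0.35,0.40,0.10,0,0
0,0,0,0.05,0.25,0.40,0.10,0
0,0,0,0,0.05,0.25,0.45,0.15
0,0,0,0,0,0.05,0.25,0.55
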