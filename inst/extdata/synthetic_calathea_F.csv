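# Synthetic stand-in fertility matrix (F): seeds produced per plant,
# single offspring type (stage 1), prebreeding census.
seed,seedling,juvenile,prerepro,small,medium,large,xlarge
0,0,0,0,3,10,20,35
0,0,0,0,0,0,0,0
0,0,0,0,0,0,0,0
0,0,0,0,0,0,0,0
0,0,0,0,0,0,0,0
0,0,0,0,0,0,0,0
0,0,0,0,0,0,0,0
0,0,0,0,0,0,0,0
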