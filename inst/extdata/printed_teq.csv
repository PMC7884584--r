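species,teq_pg_per_g
nile_tilapia,1.79
pollock,2.14
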