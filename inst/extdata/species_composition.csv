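species,display_name,country,n_batches,n_samples,glaze_pct_mean,glaze_pct_sd,fat_pct_mean,fat_pct_sd,dry_weight_pct_mean,dry_weight_pct_sd
nile_tilapia,Nile tilapia,China,18,180,30.71,1.89,1.39,0.47,18.39,1.71
panga,Panga,Vietnam/China,27,270,27.50,4.63,1.09,0.73,10.86,2.19
pacific_cod,Pacific cod,China,13,130,27.50,3.54,0.50,0.06,16.79,0.29
pollock,Pollock,China,12,120,35.00,0.00,0.67,0.09,8.60,1.42
yellowfin_sole,Yellowfin sole,China,9,90,25.00,0.00,1.07,0.17,11.25,1.13
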