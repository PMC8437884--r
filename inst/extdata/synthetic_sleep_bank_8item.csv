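# parameterization: intercept
# category_base: 1
# mean_T: 50
# sd_T: 10
item_id,n_categories,slope,intercept_1,intercept_2,intercept_3,intercept_4,specific_slope_init
item1,5,3.39,-3.35970563888011,-4.34053489189183,-5.15146510810816,-6.13229436111989,1
item2,5,2.58,-2.22570563888011,-3.20653489189184,-4.01746510810816,-4.99829436111989,1
item3,5,2.8,-2.53370563888011,-3.51453489189184,-4.32546510810816,-5.30629436111989,1
item4,5,2.51,-2.12770563888011,-3.10853489189184,-3.91946510810816,-4.90029436111989,1
item5,5,2.3,-1.83370563888011,-2.81453489189184,-3.62546510810816,-4.60629436111989,1
item6,5,2.47,-2.07170563888011,-3.05253489189184,-3.86346510810816,-4.84429436111989,1
item7,5,2.37,-1.93170563888011,-2.91253489189184,-3.72346510810816,-4.70429436111989,1
item8,5,2.77,-2.49170563888011,-3.47253489189184,-4.28346510810816,-5.26429436111989,1
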