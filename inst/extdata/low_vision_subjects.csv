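subject,acuity_logmar,cs_pelli_robson,slope,slope_ci_lo,slope_ci_hi,null_deviance,residual_deviance,reduced_deviance_ratio
LV1,0.8,1.65,6.45,1.91,10.99,70.81353,52.82475,0.25
LV2,1.28,0.6,1.57,0.56,2.57,265.9621,255.7521,0.04
LV3,1.14,0.3,3.23,2.29,4.16,337.3001,276.5907,0.18
LV4,1.16,1.05,5.60,4.00,7.19,265.9621,178.1817,0.33
LV5,1.5,0.3,5.56,3.87,7.24,338.7891,267.4427,0.21
LV6,1.36,0.8,3.79,2.68,4.90,326.7091,266.4454,0.18
LV7,1.44,0.2,2.27,1.15,3.39,346.5096,327.496,0.05
LV8,1.54,0.65,3.04,2.05,4.02,344.266,302.3751,0.12
LV9,1.66,0.57,2.53,1.44,3.62,324.338,302.1003,0.07
LV10,1.02,1.55,11.03,5.25,16.81,124.2173,72.18844,0.42
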