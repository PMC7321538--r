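group,trait,unit,treatment,mean,sd,n
morphology,palisade_thickness,um,LN,17.069,1.283,7
morphology,palisade_thickness,um,MN,32.867,0.173,7
morphology,palisade_thickness,um,HN,24.490,1.825,7
morphology,spongy_thickness,um,LN,42.551,2.194,7
morphology,spongy_thickness,um,MN,70.378,0.182,7
morphology,spongy_thickness,um,HN,56.518,0.189,7
morphology,palisade_spongy_ratio,dimensionless,LN,0.401,0.002,7
morphology,palisade_spongy_ratio,dimensionless,MN,0.467,0.016,7
morphology,palisade_spongy_ratio,dimensionless,HN,0.433,0.016,7
diffusion,gs,mol CO2 m-2 s-1,LN,0.05,0.02,7
diffusion,gs,mol CO2 m-2 s-1,MN,0.03,0.02,7
diffusion,gs,mol CO2 m-2 s-1,HN,0.03,0.02,7
diffusion,gm,mol CO2 m-2 s-1,LN,0.09,0.01,7
diffusion,gm,mol CO2 m-2 s-1,MN,0.26,0.04,7
diffusion,gm,mol CO2 m-2 s-1,HN,0.36,0.02,7
diffusion,Rd,umol CO2 m-2 s-1,LN,1.0,0.04,7
diffusion,Rd,umol CO2 m-2 s-1,MN,0.52,0.02,7
diffusion,Rd,umol CO2 m-2 s-1,HN,0.57,0.03,7
diffusion,glip,mol CO2 m-2 s-1,LN,2.61,0.08,7
diffusion,glip,mol CO2 m-2 s-1,MN,5.52,0.03,7
diffusion,glip,mol CO2 m-2 s-1,HN,0.183,0.09,7
diffusion,Cc,umol mol-1,LN,199.53,8.27,7
diffusion,Cc,umol mol-1,MN,265.45,7.31,7
diffusion,Cc,umol mol-1,HN,291.58,9.15,7
diffusion,S,mol mol-1,LN,844.15,7.56,7
diffusion,S,mol mol-1,MN,1057.25,5.41,7
diffusion,S,mol mol-1,HN,860.16,3.89,7
diffusion,Sstar,mol mol-1,LN,739.39,95.61,7
diffusion,Sstar,mol mol-1,MN,983.75,67.32,7
diffusion,Sstar,mol mol-1,HN,753.41,90.34,7
diffusion,rubisco_activity,nmol min-1 g-1,LN,0.643,0.24,7
diffusion,rubisco_activity,nmol min-1 g-1,MN,40.51,5.39,7
diffusion,rubisco_activity,nmol min-1 g-1,HN,22.51,4.89,7
diffusion,rubisco_content,ug g-1,LN,6.931,0.36,7
diffusion,rubisco_content,ug g-1,MN,10.057,0.67,7
diffusion,rubisco_content,ug g-1,HN,70.494,0.32,7
diffusion,Sc,m2 m-2,LN,8.42,1.25,7
diffusion,Sc,m2 m-2,MN,12.01,1.65,7
diffusion,Sc,m2 m-2,HN,13.15,0.56,7
diffusion,Clip,mol CO2 m-2 s-1,LN,0.31,0.06,7
diffusion,Clip,mol CO2 m-2 s-1,MN,0.46,0.02,7
diffusion,Clip,mol CO2 m-2 s-1,HN,0.02,0.01,7
diffusion,gi,mol CO2 m-2 s-1,LN,0.13,0.01,7
diffusion,gi,mol CO2 m-2 s-1,MN,0.35,0.04,7
diffusion,gi,mol CO2 m-2 s-1,HN,0.12,0.05,7
diffusion,gm_per_rubisco,mmol CO2 m-2 s-1 per ug g-1,LN,12.99,1.23,7
diffusion,gm_per_rubisco,mmol CO2 m-2 s-1 per ug g-1,MN,25.81,1.90,7
diffusion,gm_per_rubisco,mmol CO2 m-2 s-1 per ug g-1,HN,5.12,0.78,7
photosynthesis,Amax,umol m-2 s-1,LN,2.378,0.261,7
photosynthesis,Amax,umol m-2 s-1,MN,3.437,0.241,7
photosynthesis,Amax,umol m-2 s-1,HN,2.600,0.165,7
photosynthesis,CE,mol mol-1,LN,0.017,0.002,7
photosynthesis,CE,mol mol-1,MN,0.022,0.003,7
photosynthesis,CE,mol mol-1,HN,0.018,0.005,7
photosynthesis,Gamma_star,umol mol-1,LN,124.399,8.014,7
photosynthesis,Gamma_star,umol mol-1,MN,99.259,10.957,7
photosynthesis,Gamma_star,umol mol-1,HN,122.121,21.084,7
photosynthesis,Jmax,umol mol-1,LN,66.558,6.123,7
photosynthesis,Jmax,umol mol-1,MN,74.518,15.599,7
photosynthesis,Jmax,umol mol-1,HN,63.334,23.251,7
photosynthesis,Vcmax,umol mol-1,LN,16.480,1.821,7
photosynthesis,Vcmax,umol mol-1,MN,20.771,2.939,7
photosynthesis,Vcmax,umol mol-1,HN,16.830,5.058,7
photosynthesis,Jmax_over_Vcmax,dimensionless,LN,4.059,0.127,7
photosynthesis,Jmax_over_Vcmax,dimensionless,MN,3.527,0.337,7
photosynthesis,Jmax_over_Vcmax,dimensionless,HN,4.329,0.106,7
photosynthesis,SLN,g m-2,LN,0.890,0.130,7
photosynthesis,SLN,g m-2,MN,1.245,0.006,7
photosynthesis,SLN,g m-2,HN,2.178,0.348,7
pigments,neoxanthin,ug cm-2,LN,0.362,0.129,7
pigments,neoxanthin,ug cm-2,MN,0.865,0.265,7
pigments,neoxanthin,ug cm-2,HN,1.643,0.332,7
pigments,violaxanthin,ug cm-2,LN,0.913,0.124,7
pigments,violaxanthin,ug cm-2,MN,0.267,0.195,7
pigments,violaxanthin,ug cm-2,HN,0.493,0.458,7
pigments,antheraxanthin,ug cm-2,LN,0.213,0.019,7
pigments,antheraxanthin,ug cm-2,MN,0.043,0.072,7
pigments,antheraxanthin,ug cm-2,HN,0.153,0.079,7
pigments,lutein,ug cm-2,LN,1.284,0.352,7
pigments,lutein,ug cm-2,MN,3.018,0.970,7
pigments,lutein,ug cm-2,HN,5.852,0.926,7
pigments,zeaxanthin,ug cm-2,LN,0.194,0.023,7
pigments,zeaxanthin,ug cm-2,MN,0.032,0.048,7
pigments,zeaxanthin,ug cm-2,HN,0.073,0.201,7
pigments,chl,ug cm-2,LN,12.270,1.783,7
pigments,chl,ug cm-2,MN,31.618,2.356,7
pigments,chl,ug cm-2,HN,60.101,2.455,7
pigments,beta_carotene,ug cm-2,LN,4.08,2.14,7
pigments,beta_carotene,ug cm-2,MN,1.59,0.69,7
pigments,beta_carotene,ug cm-2,HN,2.95,0.69,7
pigments,vaz_pool,ug cm-2,LN,1.314,0.023,7
pigments,vaz_pool,ug cm-2,MN,0.332,0.035,7
pigments,vaz_pool,ug cm-2,HN,0.712,0.043,7
pigments,dep_state,dimensionless,LN,0.309,0.015,7
pigments,dep_state,dimensionless,MN,0.226,0.017,7
pigments,dep_state,dimensionless,HN,0.317,0.037,7
pigments,vaz_per_chl,dimensionless,LN,0.107,0.018,7
pigments,vaz_per_chl,dimensionless,MN,0.011,0.027,7
pigments,vaz_per_chl,dimensionless,HN,0.012,0.028,7
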