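exp,k_XgY,mu,acc,ema_published,nit_published
M1,2.562,1.932,0.680,0.390,0.386
M2,2.447,2.023,0.632,0.409,0.405
M3,2.589,1.912,0.628,0.386,0.382
M4,2.430,2.037,0.622,0.412,0.407
M5,2.723,1.818,0.565,0.367,0.364
M6,2.682,1.846,0.542,0.373,0.369
M7,2.730,1.813,0.539,0.366,0.363
M8,3.629,1.364,0.472,0.276,0.273
M9,2.995,1.653,0.443,0.334,0.331
M10,4.801,1.031,0.242,0.208,0.206
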