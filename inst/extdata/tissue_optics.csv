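class,wavelength_nm,mu_a,mu_s_prime,n
air,780,0,1e-4,1.4
air,805,0,1e-4,1.4
air,830,0,1e-4,1.4
soft_tissue,780,0.018,1.94,1.4
soft_tissue,805,0.019,1.9,1.4
soft_tissue,830,0.02,1.86,1.4
skull,780,0.011,1.55,1.4
skull,805,0.0115,1.5,1.4
skull,830,0.012,1.45,1.4
csf,780,0.0026,0.32,1.4
csf,805,0.0026,0.3,1.4
csf,830,0.0026,0.29,1.4
gray,780,0.018,2.1,1.4
gray,805,0.019,2.05,1.4
gray,830,0.02,2,1.4
white,780,0.016,5.2,1.4
white,805,0.0165,5,1.4
white,830,0.017,4.8,1.4
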