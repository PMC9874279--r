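# Idealized shelf baseline (350 m characteristic water depth), with
# bioturbation at its oxygen-scaled maximum for 120 uM bottom-water O2.
variant: idealized
temperature_C: 10
salinity: 34.2
domain_depth_cm: 150
burial_velocity_cm_kyr: 60
phi_surface: 0.95
phi_deep: 0.82
phi_attenuation_cm: 3.6
db0_cm2_yr: 10
z_mix_cm: 9.7
alpha0_yr: 290
x_irr_cm: 1.4
bottom_water_mM:
  O2: 0.12
  SO4: 28.0
j_poc_mmol_m2_d: 10
j_feooh_umol_m2_d: 1110
delta_feooh: 0.0
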