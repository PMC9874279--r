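# Santa Barbara Basin site configuration: unbioturbated sediment under
# a hypoxic (~10 uM O2) water column (496 m water depth).
variant: site
temperature_C: 10
salinity: 34.2
domain_depth_cm: 150
burial_velocity_cm_kyr: 250
phi_surface: 0.95
phi_deep: 0.82
phi_attenuation_cm: 3.6
db0_cm2_yr: 0
z_mix_cm: 0.1
alpha0_yr: 0
x_irr_cm: 3
bottom_water_mM:
  O2: 0.01
  SO4: 28.0
j_poc_mmol_m2_d: 4.6
j_feooh_umol_m2_d: 560
delta_feooh: -1.5
j_fes_umol_m2_d: 0
j_fes2_umol_m2_d: 30
delta_fes2: -0.4
j_mno2_umol_m2_d: 0
eps:
  pyrite: -0.7
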