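# Monterey Canyon site configuration: bioturbated sediment under a
# fully oxygenated water column (450 m water depth).
# Units: bottom-water concentrations in mM (mol m-3); particulate
# fluxes in umol m-2 d-1 except POC rain in mmol m-2 d-1.
variant: site
temperature_C: 10
salinity: 34.2
domain_depth_cm: 150
burial_velocity_cm_kyr: 250
phi_surface: 0.95
phi_deep: 0.82
phi_attenuation_cm: 3.6
db0_cm2_yr: 20
z_mix_cm: 10
alpha0_yr: 183
x_irr_cm: 3
bottom_water_mM:
  O2: 0.28
  SO4: 28.0
j_poc_mmol_m2_d: 8.0
j_feooh_umol_m2_d: 320
delta_feooh: -0.5
j_fes_umol_m2_d: 0
j_fes2_umol_m2_d: 30
delta_fes2: 0.0
j_mno2_umol_m2_d: 0
eps:
  pyrite: -0.4
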