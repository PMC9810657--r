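# Gas-specific physical constants used throughout the package.
# version: 1
# Solubility fits follow the ln(solubility) form
#   ln x = A1 + A2*(100/T) + A3*ln(T/100) + S*(B1 + B2*(T/100) + B3*(T/100)^2)
# with T in kelvin and S in PSU.  CH4 is fitted in the Bunsen-coefficient
# (beta, dimensionless, atm basis) form; CO2 in the volumetric-solubility
# form (K0, mol L^-1 atm^-1), each the native form of its published fit.
# Schmidt-number polynomials are 4th order in temperature (deg C),
# Sc = a + b*t + c*t^2 + d*t^3 + e*t^4, fitted separately for fresh water
# (salinity 0) and seawater (salinity 35).
version: 1
gases:
  CO2:
    molar_mass: 44.01           # g mol^-1
    sgwp_100: 1                 # CO2-equivalence factor, 100-y sustained flux
    solubility:
      form: k0_mol_l_atm
      A1: -58.0931
      A2: 90.5069
      A3: 22.2940
      B1: 0.027766
      B2: -0.025888
      B3: 0.0050578
      temp_range_k: [272.15, 313.15]
      sal_range: [0.0, 40.0]
    schmidt:
      fresh: [1923.6, -125.06, 4.3773, -0.085681, 0.00070284]
      sea:   [2116.8, -136.25, 4.7353, -0.092307, 0.0007555]
      temp_range_c: [-2.0, 40.0]
  CH4:
    molar_mass: 16.04
    sgwp_100: 45
    solubility:
      form: bunsen_beta
      A1: -67.1962
      A2: 99.1624
      A3: 27.9015
      B1: -0.072909
      B2: 0.041674
      B3: -0.0064603
      temp_range_k: [271.15, 303.15]
      sal_range: [0.0, 40.0]
    schmidt:
      fresh: [1909.4, -120.78, 4.1555, -0.080578, 0.00065777]
      sea:   [2101.2, -131.54, 4.4931, -0.08676, 0.00070663]
      temp_range_c: [-2.0, 40.0]
physical:
  kappa: 0.4                    # von Karman constant
  R_m3_atm: 8.20573e-05         # ideal-gas constant, m^3 atm K^-1 mol^-1
  t_std_k: 273.15               # standard temperature
  sc_reference: 660             # Schmidt number of CO2 at 20 C, salinity 35
  reference_salinity_sea: 35
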