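# Ion property table, version 1 (literature data, not measurements)
# crystal_radius_A: Shannon (1976) effective ionic radii, 6-coordinate, Angstrom
# viscosity_B_cm3_mol: Jones-Dole B coefficients, Jenkins & Marcus (1995), cm^3/mol x 10^-3 -> given in cm^3/mol
# hydration_energy_kJ_mol: Gibbs hydration free energy, Marcus (1991), kJ/mol
# coordination_number: typical first-shell water coordination, Ohtaki & Radnai (1993)
symbol,charge,crystal_radius_A,viscosity_B_cm3_mol,hydration_energy_kJ_mol,coordination_number
Li+,1,0.76,146.6,-475,4
Na+,1,1.02,85.5,-365,6
K+,1,1.38,-9.3,-295,7
Cs+,1,1.67,-47.3,-250,8
Mg2+,2,0.72,385.1,-1830,6
Ca2+,2,1.00,284.2,-1505,7
Sr2+,2,1.18,272.0,-1380,8
Ba2+,2,1.35,229.0,-1250,9
Zn2+,2,0.74,361.0,-1955,6
Cl-,-1,1.81,-5.0,-340,6
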