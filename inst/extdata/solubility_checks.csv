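gas,temp_k,salinity,quantity,value
CH4,274.15,0.0,beta,5.576904e-02
CO2,274.15,0.0,k0_mol_l_atm,7.458301e-02
CH4,274.15,35.0,beta,4.332466e-02
CO2,274.15,35.0,k0_mol_l_atm,6.218898e-02
CH4,278.15,0.0,beta,4.966064e-02
CO2,278.15,0.0,k0_mol_l_atm,6.407691e-02
CH4,278.15,35.0,beta,3.890439e-02
CO2,278.15,35.0,k0_mol_l_atm,5.358204e-02
CH4,283.15,0.0,beta,4.350064e-02
CO2,283.15,0.0,k0_mol_l_atm,5.366131e-02
CH4,283.15,35.0,beta,3.440293e-02
CO2,283.15,35.0,k0_mol_l_atm,4.506922e-02
CH4,288.15,0.0,beta,3.860897e-02
CO2,288.15,0.0,k0_mol_l_atm,4.552621e-02
CH4,288.15,35.0,beta,3.079005e-02
CO2,288.15,35.0,k0_mol_l_atm,3.843845e-02
CH4,293.15,0.0,beta,3.469241e-02
CO2,293.15,0.0,k0_mol_l_atm,3.909877e-02
CH4,293.15,35.0,beta,2.786687e-02
CO2,293.15,35.0,k0_mol_l_atm,3.321523e-02
CH4,298.15,0.0,beta,3.153588e-02
CO2,298.15,0.0,k0_mol_l_atm,3.396652e-02
CH4,298.15,35.0,beta,2.548585e-02
CO2,298.15,35.0,k0_mol_l_atm,2.905893e-02
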