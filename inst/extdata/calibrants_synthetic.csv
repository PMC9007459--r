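# SYNTHETIC calibrant table: plausible native charge states and
# helium-frame literature CCS values for the usual TWIMS calibrant
# proteins (beta-lactoglobulin monomer/dimer, cytochrome c, serum albumin).
# Drift times are generated in software (genCalibrants); none of these
# rows is a measured value.
name,mass_da,charge,lit_ccs_nm2
cytochrome_c,12358,6,13.3
cytochrome_c,12358,7,13.9
beta_lactoglobulin,18363,7,17.0
beta_lactoglobulin,18363,8,17.5
beta_lactoglobulin_dimer,36726,11,26.9
beta_lactoglobulin_dimer,36726,12,27.5
serum_albumin,66430,14,39.4
serum_albumin,66430,15,40.5
serum_albumin,66430,16,41.5
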