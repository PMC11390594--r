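# Reference parameterisation of the senescence network (arbitrary units).
# Calibrated once against the twelve phenotype criteria; these values,
# not the code, are the quantitative contract.
# Condition inputs (RAS_input, DDR_input, kDDRF, kRASF, kDDRFRAS) hold the
# pre-induction baseline; induction presets override them (see
# configure_condition).
parameter,value
RAS_input,0
DDR_input,0
kDDRF,0.01
kRASF,0.5
kDDRFRAS,0.1
d_DDR,1
b_p53,0.5
a_NF,0.8
V_p53,0.03
K_p53,1
k_dp53,0.2
d_p53,0.4
d_pp53,0.3
b_p21,0.05
V_p21,1.2
K_p21,2
d_p21,0.3
b_p38,0.6
theta,0.3
V_p38,0.4
K_p38,1
phi,0.2
alpha,0.04
k_dp38,0.3
d_p38,0.3
d_pp38,0.3
b_p16,0.05
V_p16,0.8
K_p16,2
d_p16,0.15
b_NOTCH,1
k_cleave,0.5
d_NOTCH,0.5
d_NICD,1
b_NF,0.5
V_NF,3
K_NF,1
psi,100
k_dNF,0.2
d_NF,0.1
d_pNF,0.5
b_IL6,0.25
V_IL6,8
K_IL6,6
d_IL6,0.5
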