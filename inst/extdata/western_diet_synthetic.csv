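metabolite,mM
glc_D_e,55.0
fru_e,12.0
sucr_e,8.0
strch1_e,20.0
ocdca_e,6.0
ocdcea_e,7.5
ttdca_e,2.5
hdca_e,9.0
ala_L_e,4.5
arg_L_e,2.4
asp_L_e,3.8
cys_L_e,0.9
glu_L_e,6.1
gly_e,3.5
his_L_e,1.2
ile_L_e,2.3
leu_L_e,3.9
lys_L_e,3.2
met_L_e,1.1
phe_L_e,2.0
pro_L_e,3.4
ser_L_e,2.6
thr_L_e,2.1
trp_L_e,0.6
tyr_L_e,1.6
val_L_e,2.8
k_e,30.0
na1_e,40.0
cl_e,35.0
ca2_e,10.0
mg2_e,4.0
pi_e,12.0
so4_e,3.0
fe2_e,0.2
zn2_e,0.1
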