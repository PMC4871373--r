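ks_bck2 = 0.0067499999999999999
kd_bck2 = 0.5
ks_bud_e = 0.33000000000000002
kd_bud = 0.01
ks_cdc20 = 0.0060000000000000001
ks_cdc20_m1 = 0.59999999999999998
kd_cdc20 = 0.29999999999999999
ks_cki = 0.024
ks_cki_swi5 = 0.23999999999999999
kd_cki = 0.0050000000000000001
kd_ckip = 1.7
ks_cki_gal = 0
ks_clb2 = 0.0066
ks_clb2_m1 = 0.043999999999999997
kd_clb2 = 0.0030000000000000001
kd_clb2_20 = 0.14000000000000001
kd_clb2_20_i = 0.036600000000000001
kd_clb2_h1 = 0.59999999999999998
ks_clb5 = 0.00059999999999999995
ks_clb5_bf = 0.029000000000000001
kd_clb5 = 0.012
kd_clb5_20 = 0.10000000000000001
kd_clb5_20_i = 0.014999999999999999
ks_cln2 = 0
ks_cln2_bf = 0.27000000000000002
kd_cln2 = 0.12
ks_cln3 = 0.11
kd_cln3 = 0.40000000000000002
ks_ori_e = 2
kd_ori = 0.059999999999999998
ks_pds1 = 0.029999999999999999
kd_pds1 = 0.050000000000000003
kd_pds1_20 = 3
kd_pds1_20_i = 0.29999999999999999
ks_polo_m1 = 0.029999999999999999
kd_polo = 0.01
kd_polo_h1 = 0.10000000000000001
ks_swi5 = 0.0050000000000000001
ks_swi5_m1 = 0.080000000000000002
kd_swi5 = 0.080000000000000002
ks_spn = 0.10000000000000001
kd_spn = 0.059999999999999998
mu = 0.0069300000000000004
gamma = 1
gamma_cki = 2
gamma_apc = 0.80000000000000004
gamma_tem1 = 0.10000000000000001
om_a_apc_b2 = 0.65000000000000002
om_i_apc = 1
om_a_cdc15_14 = 15
om_i_cdc15 = 1
om_i_cdc15_b2 = 0.25
om_a_cdh1 = 1
om_a_cdh1_14 = 4.2999999999999998
om_i_cdh1_e = 1
om_i_cdh1_n3 = 1
om_i_cdh1_n2 = 0.62219999999999998
om_i_cdh1_b5 = 4.5
om_i_cdh1_b2 = 2.7999999999999998
om_p_cki_n3 = 4.2000000000000002
om_p_cki_k2 = 0.40000000000000002
om_p_cki_n2 = 0.35560000000000003
om_p_cki_b5 = 1.5
om_p_cki_b2 = 2.2000000000000002
om_dp_cki = 1
om_dp_cki_14 = 1.8
om_a_mad2 = 20
om_i_mad2 = 0.40000000000000002
om_a_mcm1_b2 = 5
om_i_mcm1 = 3
om_p_net1_b2 = 0.125
om_p_net1_en = 1
om_p_net1_15 = 0.029999999999999999
om_dp_net1 = 0.10000000000000001
om_dp_net1_14 = 0.10000000000000001
om_dp_net1_px = 3
om_a_polo_b2 = 5
om_i_polo = 1
om_a_ppx = 1
om_i_ppx_p1 = 3
om_p_sbf_b2 = 2.5
om_dp_sbf = 1
om_a_swi5_14 = 2
om_i_swi5_b2 = 4.25
om_a_tem1_lo = 6
om_i_tem1 = 1
om_i_tem1_px = 22
om_p_whi5_n2 = 1.7778
om_p_whi5_n3 = 12
om_p_whi5_k2 = 16
om_p_whi5_b5 = 0
om_dp_whi5 = 1
om_dp_whi5_14 = 0.5
apc_t = 25
cdc14_t = 2
cdc15_t = 1
cdh1_t = 1
esp1_t = 0.5
mcm1_t = 1
net1_t = 3.5499999999999998
ppx_t = 1
sbf_t = 1
tem1_t = 2
whi5_t = 2.5
mad2_t = 25
d_cln3 = 1
e_bud_b5 = 0.25
e_bud_n2 = 0.44440000000000002
e_bud_n3 = 0.20000000000000001
e_ori_b2 = 0.34999999999999998
e_ori_b5 = 0.20999999999999999
j_cln3 = 6
j_spn = 0.26000000000000001
k_ez = 0.40000000000000002
k_ez2 = 0.40000000000000002
rho_14_net1 = 1
sigma = 10
sigma_net1 = 8
k_flag = 0.80000000000000004
k_tr = 0.14999999999999999
k_dm = 0.69999999999999996
div_sd = 0.050000000000000003
c_vol = 28
mmin_cln3 = 0
mmin_bck2 = 0
mmin_cln2 = 5
mmin_clb5 = 5
mmin_clb2 = 5
mmin_cki = 5
mmin_swi5 = 0
mmin_cdc20 = 0
mmin_pds1 = 5
mmin_polo = 0
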