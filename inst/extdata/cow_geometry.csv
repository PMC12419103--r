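name,from,to,length_m,radius_m,role
ICA_L,n_ica_l0,n_ica_l1,0.100,0.00250,inlet
ICA_R,n_ica_r0,n_ica_r1,0.100,0.00250,inlet
VA_L,n_va_l0,n_va_l1,0.150,0.00170,inlet
VA_R,n_va_r0,n_va_r1,0.150,0.00170,inlet
ICA_intracranial_L,n_ica_l1,n_carotid_l,0.030,0.00200,internal
ICA_intracranial_R,n_ica_r1,n_carotid_r,0.030,0.00200,internal
V4_L,n_va_l1,n_ba0,0.035,0.00150,internal
V4_R,n_va_r1,n_ba0,0.035,0.00150,internal
BA,n_ba0,n_ba1,0.030,0.00160,internal
MCA_M1_L,n_carotid_l,n_mca_l_out,0.025,0.00140,outlet
MCA_M1_R,n_carotid_r,n_mca_r_out,0.025,0.00140,outlet
ACA_A1_L,n_carotid_l,n_acom_l,0.014,0.00110,internal
ACA_A1_R,n_carotid_r,n_acom_r,0.014,0.00110,internal
ACA_A2_L,n_acom_l,n_aca_l_out,0.025,0.00105,outlet
ACA_A2_R,n_acom_r,n_aca_r_out,0.025,0.00105,outlet
AComm,n_acom_l,n_acom_r,0.003,0.00070,internal
PCA_P1_L,n_ba1,n_pca_l,0.008,0.00110,internal
PCA_P1_R,n_ba1,n_pca_r,0.008,0.00110,internal
PCA_P2_L,n_pca_l,n_pca_l_out,0.025,0.00105,outlet
PCA_P2_R,n_pca_r,n_pca_r_out,0.025,0.00105,outlet
PComm_L,n_carotid_l,n_pca_l,0.015,0.00070,internal
PComm_R,n_carotid_r,n_pca_r,0.015,0.00070,internal
SCA_L,n_ba1,n_sca_l_out,0.015,0.00060,outlet
SCA_R,n_ba1,n_sca_r_out,0.015,0.00060,outlet
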