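model_id,run,bias,seasonal_diff
bccr_bcm2_0,1,-0.9,1
cccma_cgcm3_1,1,1.36,0.61
cccma_cgcm3_1,2,-0.33,0.39
cccma_cgcm3_1,3,3.9,1.35
cnrm_cm3,1,-1.35,1.21
csiro_mk3_0,1,-4.4,1.9
csiro_mk3_0,2,2.15,0.49
csiro_mk3_5,1,-0.51,0.66
csiro_mk3_5,2,-1.96,0.66
csiro_mk3_5,3,1.29,0.14
gfdl_cm2_0,1,-0.98,0.25
gfdl_cm2_0,2,0.19,0.54
gfdl_cm2_1,1,-0.9,0.76
gfdl_cm2_1,2,3,0.19
giss_aom,1,2.4,1.54
giss_model_e_r,1,1.95,0.67
giss_model_e_r,2,-1.94,2.12
giss_model_e_r,3,3.42,0.71
iap_fgoals1_0_g,1,-1.02,0.6
inmcm3_0,1,-1.24,0.46
ipsl_cm4,1,1.53,0.71
ipsl_cm4,2,0.67,0.27
miroc3_2_medres,1,-0.18,0.11
miroc3_2_medres,2,-3.81,0.32
miroc3_2_medres,3,4.25,0.78
miub_echo_g,1,0.07,0.27
miub_echo_g,2,5.6,2.4
mpi_echam5,1,3.12,0.76
mpi_echam5,2,0.09,0.08
mpi_echam5,3,0.02,0.5
mri_cgcm2_3_2a,1,0.79,0.51
mri_cgcm2_3_2a,2,-3.35,0.72
mri_cgcm2_3_2a,3,2.14,0.37
ncar_ccsm3_0,1,4.96,0.12
ncar_ccsm3_0,2,-1.31,0.13
ncar_ccsm3_0,3,-1.99,0.81
ncar_ccsm3_0,4,-0.66,0.24
ncar_pcm1,1,1.02,0.13
ncar_pcm1,2,-1.86,2.76
ukmo_hadcm3,1,-1.79,1.08
ukmo_hadgem1,1,3.7,0.58
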