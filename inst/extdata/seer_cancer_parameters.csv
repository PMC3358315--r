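cancer,histotype,age_min,chi2_dof,c,c_se,m,m_se,n,n_se,sigma,sigma_se,r_sex,r_sex_se,r_race,r_race_se,f_year,f_year_se
lung_scc,SCC,30,2.71,79.1,0.3,11.41,0.10,0.57,0.03,7.3,0.1,0.25,0.00,1.33,0.02,-6.86,0.55
lung_ac,AC,30,2.63,83.8,0.4,9.79,0.09,0.65,0.03,9.4,0.2,0.64,0.01,0.89,0.02,33.20,0.74
stomach_ac,AC,30,1.09,100.4,1.3,8.28,0.14,1.79,0.16,11.6,1.1,0.37,0.00,1.03,0.02,-9.48,0.49
esophagus_scc,SCC,30,1.07,89.6,1.2,12.86,0.34,0.83,0.04,30.1,1.3,0.30,0.01,2.75,0.08,-15.98,0.87
esophagus_ac,AC,30,0.45,106.2,1.6,9.93,0.19,1.05,0.04,40.2,1.8,0.10,0.00,0.10,0.00,151.85,2.70
colon_ac,AC,30,1.65,83.4,0.3,7.99,0.05,1.23,0.10,3.8,0.1,0.74,0.00,1.07,0.01,-6.17,0.22
rectum_ac,AC,30,1.14,85.2,0.7,9.67,0.13,1.36,0.03,14.2,0.5,0.55,0.00,0.42,0.01,-7.28,0.42
pancreas_ac,AC,30,1.07,89.2,0.8,10.02,0.14,1.42,0.04,14.9,0.7,0.73,0.01,0.94,0.02,-3.41,0.45
liver_ac,AC,30,1.01,99.6,2.0,9.76,0.25,1.09,0.07,29.9,2.2,0.23,0.00,0.92,0.03,85.55,2.34
kidney_ac,AC,30,1.14,97.3,0.8,7.57,0.08,0.75,0.04,12.1,0.3,0.46,0.00,0.62,0.01,36.30,0.73
breast_ductal_ac,AC,20,3.28,58.3,0.3,8.64,0.08,1.25,0.01,8.7,0.1,1.00,0.00,0.82,0.01,22.36,0.36
breast_lobular_ac,AC,30,1.82,64.1,0.7,11.63,0.24,1.16,0.00,24.9,0.6,1.00,0.00,0.41,0.01,71.22,1.01
prostate_ac,AC,40,15.23,67.5,0.2,14.08,0.16,0.87,0.02,4.5,0.1,1.00,0.00,1.55,0.03,43.75,1.05
ovarian_ac,AC,25,1.39,106.0,1.6,5.95,0.09,0.73,0.07,10.8,0.4,1.00,0.00,0.30,0.01,-1.39,0.56
corpus_uteri_ac,AC,30,0.77,74.2,10.6,8.42,1.38,0.90,0.03,100.5,10.9,1.00,0.00,0.15,0.03,36.99,2.57
cervix_uteri_scc,SCC,15,9.48,37.9,0.8,12.01,0.51,0.96,0.01,30.4,1.0,1.00,0.00,0.97,0.04,-49.99,0.64
cervix_uteri_ac,AC,30,1.79,78.7,0.5,8.80,0.10,0.73,0.02,9.6,0.2,1.00,0.00,0.24,0.01,-7.13,0.49
larynx_scc,SCC,15,0.87,81.7,0.5,11.09,0.13,0.83,0.02,17.2,0.3,0.12,0.00,1.04,0.02,-6.71,0.54
anal_scc,SCC,15,0.44,91.8,5.5,11.96,0.85,1.12,0.01,272.5,21.9,1.36,0.04,0.35,0.03,279.69,15.02
vulvar_scc,SCC,15,0.94,106.4,7.0,6.02,0.28,1.47,0.03,73.8,5.2,1.00,0.00,0.37,0.02,96.00,2.43
lip_scc,SCC,15,0.42,132.3,1.2,7.15,0.07,0.00,0.00,14.2,0.2,0.10,0.00,0.10,0.00,-30.12,0.57
tongue_scc,SCC,15,0.73,99.4,1.3,8.89,0.16,0.72,0.03,26.7,0.8,0.31,0.01,0.43,0.02,29.52,1.22
floor_of_mouth_scc,SCC,15,0.49,89.8,1.3,11.97,0.29,0.71,0.03,44.4,1.3,0.24,0.01,0.53,0.04,-19.79,0.87
gum_other_mouth_scc,SCC,15,0.58,96.0,1.8,11.34,0.32,1.00,0.04,43.6,2.2,0.44,0.01,0.47,0.03,-5.05,1.02
tonsil_scc,SCC,15,0.58,96.2,1.5,10.09,0.21,0.65,0.03,45.3,1.4,0.18,0.01,0.77,0.04,47.37,2.55
hypopharynx_scc,SCC,15,0.44,98.9,1.3,11.21,0.22,0.47,0.04,35.2,1.0,0.12,0.00,0.74,0.04,-11.06,1.01
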