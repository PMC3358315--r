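cancer,year,in_situ,localized,regional,distant,unstaged
lung_scc,1983,0.4,20.9,40.7,24.1,14.0
lung_scc,2003,0.3,24.6,46.5,24.1,4.5
lung_ac,1983,,20.4,34.4,37.2,8
lung_ac,2003,,19.5,38.0,38.8,3.7
stomach_ac,1973,0.3,15.9,33.1,32.6,18.2
stomach_ac,2003,0.9,22.0,33.0,34.5,9.6
esophagus_scc,1973,0.2,27.6,20.9,22.6,28.6
esophagus_scc,2003,0.8,23.5,33.0,26.2,16.5
esophagus_ac,1973,,12.5,22.5,47.5,17.5
esophagus_ac,2003,2,23.7,30.5,31.6,12.1
colon_ac,1973,2.5,27.5,31.8,20.8,17.4
colon_ac,2003,6.2,38.0,34.8,17.6,3.4
rectum_ac,1973,4,37.6,26.1,15.7,16.6
rectum_ac,2003,6.9,43.3,30.3,14.0,5.5
pancreas_ac,1973,,11.3,17.2,44.6,26.9
pancreas_ac,2003,0.1,7.1,26.6,55.0,11.3
liver_ac,1973,,13.9,15.7,33.4,36.9
liver_ac,2003,,40.7,25.4,18.0,15.9
kidney_ac,1973,,40.4,17.9,27.8,13.8
kidney_ac,2003,0.1,62.6,15.3,18.4,3.7
breast_ductal_ac,1973,4.5,39.1,40.3,4.0,12.1
breast_ductal_ac,1996,16.3,54.9,24.1,3.2,1.5
breast_ductal_ac,2003,19,50.6,26.2,3.3,1.0
breast_lobular_ac,1973,26.4,32.8,25.6,4.2,10.9
breast_lobular_ac,2003,18,47.6,29.5,4.2,0.8
prostate_ac,1983,,75.0,17.9,7.0,
prostate_ac,2003,,94.0,3.4,2.6,
ovarian_ac,1973,,24.6,7.7,54.5,13.2
ovarian_ac,2003,0.4,14.5,6.6,76.6,2.0
corpus_uteri_ac,1973,7.3,69.7,3.9,3.7,15.4
corpus_uteri_ac,2003,1.5,74.3,15.8,4.8,3.7
cervix_uteri_ac,1973,2.4,44.7,24.7,8.2,20.0
cervix_uteri_ac,1995,55.2,31.4,7.6,1.5,4.1
cervix_uteri_ac,1996,,62.7,22.3,7.7,7.3
cervix_uteri_ac,2003,,62.4,22.0,8.7,6.9
cervix_uteri_scc,1973,63.2,19.6,9.5,2.5,5.2
cervix_uteri_scc,1995,88.2,6.2,4.1,0.7,0.8
cervix_uteri_scc,1996,,52.1,36.3,6.6,5.0
cervix_uteri_scc,2003,,47.3,40.1,9.3,3.3
larynx_scc,1973,3,52.9,25.3,3.0,12.5
larynx_scc,2003,5.9,41.5,46.5,3.5,2.6
anal_scc,1973,6.4,46.8,31.9,4.3,10.6
anal_scc,2003,29.2,36.3,22.4,6.9,5.2
vulvar_scc,1973,20.5,43.9,19.7,1.5,14.4
vulvar_scc,2003,63.5,20.8,10.8,1.3,1.8
lip_scc,1973,1.4,65.5,7.4,0.8,24.9
lip_scc,2003,6.6,75.3,12.6,1.1,4.4
tongue_scc,1973,1.0,32.8,36.1,11.7,18.4
tongue_scc,2003,2.8,34.4,49.1,10.7,2.9
floor_of_mouth_scc,1973,1.6,29.5,41.0,8.2,19.7
floor_of_mouth_scc,2003,6.2,38.1,46.0,5.2,4.5
gum_other_mouth_scc,1973,1.2,35.6,36.4,10.7,16.2
gum_other_mouth_scc,2003,3.8,34.3,49.7,6.2,6.0
tonsil_scc,1973,2.3,15.4,46.3,21.7,14.3
tonsil_scc,2003,1.0,12.8,73.1,10.3,2.8
hypopharynx_scc,1973,,17.1,40.3,27.1,15.5
hypopharynx_scc,2003,0.8,11.6,66.9,17.2,3.4
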