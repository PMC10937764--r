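label,type,x1,n1,x2,n2,mean1,sd1,mean2,sd2,published_p
mean_age_years,continuous,,100,,20,55.66,17.7,66.73,14.8,0.011
share_of_males,proportion,73,100,11,20,,,,,0.048
mean_inpatient_duration_days,continuous,,100,,20,3.76,7.14,6.11,5.20,0.175
mean_stone_size_mm,continuous,,100,,20,8.24,4.46,10.12,4.72,0.097
share_proximal_ureteric_stones,proportion,33,100,8,20,,,,,0.550
share_mid_ureteric_stones,proportion,16,100,7,20,,,,,0.049
share_distal_ureteric_stones,proportion,51,100,5,20,,,,,0.033
complications,proportion,4,100,1,20,,,,,0.839
complete_clearance,proportion,66,100,14,20,,,,,0.731
re_intervention,proportion,9,100,3,20,,,,,0.418
re_admission,proportion,18,100,4,20,,,,,0.834
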