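tester,age_years,monitoring_h,normal_h,abnormal_h,snoring_h,accuracy_snore_pct,normal_ratio_pct,accuracy_state_pct
1,20,7.7,6,1.7,0.5,93.5,77.9,93.2
2,21,7.5,5.6,1.9,0.3,96.0,74.7,94.4
3,21,6.8,4.9,1.9,0.1,98.5,72.1,91.9
4,20,6,2.4,3.6,2.2,96.4,40,90.2
5,31,7.5,5.5,2,1,90.8,73.3,94.9
6,34,8,4.2,3.8,3.2,97.6,52.5,92.2
7,58,5,2.8,2.2,1.8,97.5,56,95.2
8,60,6.8,2.3,4.5,3.8,98.2,33.8,92.7
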