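subject_id,group,age,body_length,body_weight,chest_circumference,vlc_actual,biceps_tense,biceps_rest,stange,genchi,splits,crab,forward_bend
a01,athlete,13.19,150.11,36.34,71.68,2.53,22.27,20,50.21,41.2,-4.75,52.05,17.58
a02,athlete,12.35,151.75,39.11,71.94,2.51,19.18,19.12,53.89,26.47,-0.8,52.31,7.51
a03,athlete,11.2,149.03,44.88,71.15,2.7,25.84,22.68,58.07,34.61,9.87,46.45,17.01
a04,athlete,11.42,148.63,34.56,70,1.91,23.37,22.44,52.87,28.67,-1.37,38.05,13.01
a05,athlete,11.29,152.09,36.06,72.65,2.55,21.21,19.49,61.82,13.94,-3.42,49.31,24.29
a06,athlete,11.29,157.49,49.62,82.34,3.12,23.86,21.07,52.34,37.27,-6.86,54.48,14.78
a07,athlete,13.24,150.49,37.25,74.44,2.79,21.92,19.87,66.76,33.04,-6.85,67.39,12.54
a08,athlete,12.29,158.76,40.12,74.44,2.7,26.68,23.45,50.71,33.97,-4.11,47.82,18.18
a09,athlete,11.07,162.4,56.31,79.28,3.47,22.56,19.88,50.66,36.95,-0.76,55.91,19.06
a10,athlete,11.95,150.75,36.01,73.88,1.98,21.2,20.75,44.28,29.77,-3.29,43.55,20.12
a11,athlete,11.66,142.49,29.48,69.18,2.2,19.53,19.45,60.36,10.24,-5.02,57.83,18.66
a12,athlete,10.5,149,44.33,68.69,2.74,25.87,22.89,27.09,27.82,-2.42,50.32,18.57
a13,athlete,10.78,149.66,31.88,72.8,2.62,20.75,20.52,54.9,31.01,-1.48,57.38,21.1
a14,athlete,11.88,149.59,43.97,73.26,2.53,23.67,21,50.13,12.6,-1.32,38.8,21.41
a15,athlete,11.79,142.88,31.16,68.36,1.64,22.61,20.58,53.88,29.13,-6.01,45.54,22.03
c01,control,11.96,143.91,40.58,75.09,1.67,20.47,20.36,41.39,14.83,6.58,56.03,3.29
c02,control,12.38,155.59,43.66,81.47,2.29,21.5,21.17,36.13,34.76,2,57.4,16.85
c03,control,11.68,151.01,38.98,71.49,1.83,21.87,21.35,52.93,17.43,7.26,64.88,5.43
c04,control,11.6,155.56,48.79,72.91,2.76,21.08,21,37.3,13.8,-5.77,39.82,2.96
c05,control,11.52,160.42,56.66,79.54,2.04,23.75,22.75,33.52,15.65,3.66,50.76,6.35
c06,control,11.69,147.4,36.49,73.17,1.94,20.86,20.21,55.33,29.58,4.41,45.22,7.18
c07,control,12.14,147.82,37.04,75.66,2.06,18.82,18.47,37.93,35.91,-5.91,53.48,1.14
c08,control,12.06,148.21,36.23,69.11,1.69,19.1,18.81,37.67,33.05,3.15,81.03,1.51
c09,control,12.6,158.16,49.55,81.43,2.17,21.37,21.14,37.72,18.09,4.7,42.24,13.14
c10,control,11.1,150.72,35.17,79.59,1.89,24.59,22.3,57.88,15.14,10.49,70.93,8.23
c11,control,11.95,162.53,50.18,80.55,2.14,21.64,21.21,35.16,9.37,2.07,43.84,7.55
c12,control,12.13,155.1,42.22,79.35,1.94,26.4,25.25,60.12,35.86,7.36,71.73,7.63
c13,control,12.73,149.96,43.54,70.48,1.61,18.94,18.68,39.42,32.63,3.37,62.15,8.11
c14,control,12.91,157.58,50.53,81.17,1.77,21.84,21.35,43.82,17.41,-4.25,79.33,17.6
c15,control,12.65,153.55,44.56,74.22,1.67,21.92,21.37,60.05,13.2,1.27,46.51,1.98
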