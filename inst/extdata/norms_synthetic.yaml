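weight_norms:
- min_height: 125.0
  max_height: 130.0
  M: 27.0
  delta_R: 3.8
- min_height: 130.0
  max_height: 135.0
  M: 30.0
  delta_R: 4.0
- min_height: 135.0
  max_height: 140.0
  M: 33.0
  delta_R: 4.3
- min_height: 140.0
  max_height: 145.0
  M: 36.5
  delta_R: 4.6
- min_height: 145.0
  max_height: 150.0
  M: 40.0
  delta_R: 4.9
- min_height: 150.0
  max_height: 155.0
  M: 43.5
  delta_R: 5.2
- min_height: 155.0
  max_height: 160.0
  M: 47.0
  delta_R: 5.6
- min_height: 160.0
  max_height: 165.0
  M: 51.0
  delta_R: 6.0
- min_height: 165.0
  max_height: 170.0
  M: 55.0
  delta_R: 6.4
stange_norm:
- min_age: 5.0
  max_age: 7.0
  value: 20.0
- min_age: 7.0
  max_age: 9.0
  value: 30.0
- min_age: 9.0
  max_age: 11.0
  value: 40.0
- min_age: 11.0
  max_age: 13.0
  value: 48.0
- min_age: 13.0
  max_age: 15.0
  value: 55.0
- min_age: 15.0
  max_age: 18.0
  value: 60.0
- min_age: 18.0
  max_age: 25.0
  value: 65.0
genchi_norm:
- min_age: 5.0
  max_age: 7.0
  value: 12.0
- min_age: 7.0
  max_age: 9.0
  value: 16.0
- min_age: 9.0
  max_age: 11.0
  value: 20.0
- min_age: 11.0
  max_age: 13.0
  value: 24.0
- min_age: 13.0
  max_age: 15.0
  value: 28.0
- min_age: 15.0
  max_age: 18.0
  value: 30.0
- min_age: 18.0
  max_age: 25.0
  value: 32.0
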