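# Mean body weight (kg) by age bin and sex, for imputing missing body weight
# from demographic records. Compiled approximation of published US
# population-average anthropometric reference tables (NHANES-style survey
# means); piecewise constant over age bins. Ages outside the table are
# clamped to the nearest bin.
age_min,age_max,sex,bw_kg
18,29,M,83.4
30,39,M,86.0
40,49,M,87.9
50,59,M,88.8
60,69,M,88.2
70,79,M,84.2
80,120,M,78.0
18,29,F,71.1
30,39,F,74.9
40,49,F,76.4
50,59,F,76.8
60,69,F,76.0
70,79,F,71.9
80,120,F,65.7
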