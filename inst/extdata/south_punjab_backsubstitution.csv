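measure,sex,age,actual_p50,fitted_p50,printed_error
height,male,12,149.72,150.00,0.00
height,male,13,158.62,159.50,-0.01
height,male,14,164.74,165.00,0.00
height,male,15,166.11,165.00,0.01
height,male,16,167.79,168.00,0.00
height,female,12,152.16,152.00,0.00
height,female,13,157.87,159.00,-0.01
height,female,14,161.68,162.00,0.00
height,female,15,162.38,162.00,0.00
height,female,16,162.65,162.00,0.00
weight,male,12,37.38,35.90,0.04
weight,male,13,41.79,41.50,0.01
weight,male,14,45.28,45.23,0.00
weight,male,15,47.58,47.00,0.01
weight,male,16,49.68,49.00,0.01
weight,female,12,35.70,33.85,0.05
weight,female,13,37.73,36.00,0.05
weight,female,14,40.93,41.00,0.00
weight,female,15,44.02,43.00,0.02
weight,female,16,44.12,43.50,0.01
bmi,male,12,16.59,16.45,0.01
bmi,male,13,16.81,16.54,0.02
bmi,male,14,17.03,17.19,-0.01
bmi,male,15,17.26,16.70,0.03
bmi,male,16,17.48,17.15,0.02
bmi,female,12,15.26,14.67,0.04
bmi,female,13,15.71,15.82,-0.01
bmi,female,14,15.73,15.60,0.01
bmi,female,15,16.74,16.36,0.02
bmi,female,16,16.81,16.52,0.02
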