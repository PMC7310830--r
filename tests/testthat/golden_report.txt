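=== MUAC screening accuracy report ===

-- Participant flow --
approached 851 | absent 0 | refused 0 | missing measurements 0 | analysed 851

-- Descriptives: mean (SD) --
total  n=851  age 16.7 (1.1) y | height 163.5 (8.7) cm | weight 53.5 (9.0) kg | BMI Z -0.52 (1.19) | MUAC 25.3 (3.2) cm
male   n=456  age 16.7 (1.1) y | height 168.9 (6.7) cm | weight 54.2 (8.6) kg | BMI Z -0.86 (1.18) | MUAC 25.3 (3.1) cm
female n=395  age 16.8 (1.1) y | height 157.4 (6.3) cm | weight 52.7 (9.5) kg | BMI Z -0.13 (1.08) | MUAC 25.4 (3.2) cm

-- Prevalence (BMI Z reference) --
overweight_only        55/851 = 6.5% (4.9-8.3)
obese                  17/851 = 2.0% (1.2-3.2)
overweight_incl_obese  72/851 = 8.5% (6.7-10.5)

-- Correlation (Spearman) --
MUAC ~ BMI Z: rho 0.80 (0.77-0.82), n=851
MUAC ~ age : rho -0.01 (-0.08-0.06), n=851

-- Discrimination (AUC, DeLong CI) --
total  AUC 0.94 (0.92-0.96), band excellent
male   AUC 0.96 (0.95-0.98), band excellent
female AUC 0.93 (0.91-0.96), band excellent
bootstrap optimism -0.0006 over 100 resamples (seed 20200623); corrected AUC 0.94

-- Calibration (MUAC logistic model) --
Hosmer-Lemeshow chi2 3.86 on 8 df, p = 0.870; slope 1.00, intercept 0.00

-- Youden-optimal cutoffs and diagnostic panel --
strat     cutoff      J        sens % (CI)        spec % (CI)         PPV % (CI)         NPV % (CI)       LR+ (CI)       LR- (CI)  correct %      n
total  >=  28.05   0.75   88.9 (79.3-95.1)   86.1 (83.5-88.5)   37.2 (30.0-44.9)   98.8 (97.7-99.5) 6.41 (5.29-7.78) 0.13 (0.07-0.25)       86.4    851
male   >=  28.70   0.86   95.5 (77.2-99.9)   90.1 (86.9-92.7)   32.8 (21.6-45.7)  99.7 (98.6-100.0) 9.63 (7.15-12.98) 0.05 (0.01-0.34)       90.4    456
female >=  28.05   0.72   84.0 (70.9-92.8)   87.8 (83.9-91.1)   50.0 (38.9-61.1)   97.4 (95.0-98.9) 6.90 (5.07-9.39) 0.18 (0.10-0.34)       87.3    395

-- Pooled confusion table (rule: pooled cutoff) --
            reference+  reference-
screen+          64        108
screen-           8        671
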