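# Reference 15-rule prediabetes/diabetes model for the health-survey cohort.
# First-match semantics; the rules partition the in-range input space.
# Units: HbA1c %, FPG mg/dL, LDL mg/dL, UACR mg/g Cr, Age years.
R1: IF HbA1c <= 5.8 AND FPG <= 122.7 AND LDL <= 101 AND Mexican-American = No THEN prediabetes
R2: IF HbA1c <= 5.8 AND FPG <= 122.7 AND LDL <= 101 AND Mexican-American = Yes AND Age <= 40 THEN prediabetes
R3: IF HbA1c <= 5.8 AND FPG <= 122.7 AND LDL <= 101 AND Mexican-American = Yes AND Age > 40 THEN diabetes
R4: IF HbA1c in (5.8, 6.1] AND FPG <= 122.7 AND LDL <= 101 THEN diabetes
R5: IF HbA1c <= 6.1 AND FPG <= 122.7 AND LDL > 101 THEN diabetes
R6: IF HbA1c <= 5.6 AND FPG > 122.7 AND UACR <= 71 THEN prediabetes
R7: IF HbA1c <= 5.6 AND FPG > 122.7 AND UACR > 71 THEN diabetes
R8: IF HbA1c in (5.6, 6.1] AND FPG > 122.7 AND LDL <= 151 THEN diabetes
R9: IF HbA1c in (5.6, 6.1] AND FPG > 122.7 AND LDL > 151 THEN prediabetes
R10: IF HbA1c in (6.1, 6.4] AND LDL <= 142 AND FPG <= 108.5 AND Non-Hispanic Black = No THEN diabetes
R11: IF HbA1c in (6.1, 6.4] AND LDL <= 142 AND FPG <= 108.5 AND Non-Hispanic Black = Yes AND UACR <= 6.1 THEN prediabetes
R12: IF HbA1c in (6.1, 6.4] AND LDL <= 142 AND FPG <= 108.5 AND Non-Hispanic Black = Yes AND UACR > 6.1 THEN diabetes
R13: IF HbA1c in (6.1, 6.4] AND LDL <= 142 AND FPG > 108.5 THEN diabetes
R14: IF HbA1c in (6.1, 6.4] AND LDL > 142 THEN prediabetes
R15: IF HbA1c > 6.4 THEN diabetes
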