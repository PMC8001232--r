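# Default 45-variable cohort schema.
#
# Healthy intervals are standard adult reference ranges for each analyte;
# extreme bounds delimit clinically plausible results and define how far a
# value can deviate (they set the worst-case normalization denominator).
# Both are method parameters, documented stand-ins meant to be overridden
# per laboratory. Qualitative variables carry their category codes and the
# benign subset mapped to label 0.
variables:
  # ---- 33 blood and urine analytes -------------------------------------
  - {name: albumin,              kind: numeric, unit: g/dL,    healthy: [3.5, 5.0],   extreme: [1.0, 7.0]}
  - {name: bilirubin_direct,     kind: numeric, unit: mg/dL,   healthy: [0.1, 0.3],   extreme: [0.01, 15.0]}
  - {name: bilirubin_total,      kind: numeric, unit: mg/dL,   healthy: [0.3, 1.2],   extreme: [0.05, 30.0]}
  - {name: creatinine,           kind: numeric, unit: mg/dL,   healthy: [0.6, 1.2],   extreme: [0.2, 15.0]}
  - {name: alkaline_phosphatase, kind: numeric, unit: U/L,     healthy: [44, 147],    extreme: [5, 1200]}
  - {name: gamma_gt,             kind: numeric, unit: U/L,     healthy: [9, 48],      extreme: [2, 1500]}
  - {name: glycemia,             kind: numeric, unit: mg/dL,   healthy: [70, 100],    extreme: [30, 600]}
  - {name: got_ast,              kind: numeric, unit: U/L,     healthy: [8, 40],      extreme: [2, 2000]}
  - {name: gpt_alt,              kind: numeric, unit: U/L,     healthy: [7, 56],      extreme: [2, 2000]}
  - {name: potassium,            kind: numeric, unit: mmol/L,  healthy: [3.5, 5.1],   extreme: [1.5, 9.0]}
  - {name: total_protein,        kind: numeric, unit: g/dL,    healthy: [6.0, 8.3],   extreme: [3.0, 12.0]}
  - {name: sodium,               kind: numeric, unit: mmol/L,  healthy: [135, 145],   extreme: [110, 170]}
  - {name: quick_time,           kind: numeric, unit: s,       healthy: [11, 13.5],   extreme: [8, 60]}
  - {name: prothrombin_index,    kind: numeric, unit: '%',     healthy: [80, 120],    extreme: [10, 160]}
  - {name: inr,                  kind: numeric, unit: ratio,   healthy: [0.8, 1.2],   extreme: [0.4, 8.0]}
  - {name: urea,                 kind: numeric, unit: mg/dL,   healthy: [15, 45],     extreme: [3, 400]}
  - {name: serum_iron,           kind: numeric, unit: ug/dL,   healthy: [60, 170],    extreme: [5, 500]}
  - {name: leukocytes,           kind: numeric, unit: 10^9/L,  healthy: [4.0, 11.0],  extreme: [0.5, 300.0]}
  - {name: basophils,            kind: numeric, unit: 10^9/L,  healthy: [0.01, 0.10], extreme: [0.001, 3.0]}
  - {name: neutrophils_count,    kind: numeric, unit: 10^9/L,  healthy: [2.0, 7.5],   extreme: [0.1, 50.0]}
  - {name: neutrophils_pct,      kind: numeric, unit: '%',     healthy: [40, 75],     extreme: [5, 98]}
  - {name: eosinophils_pct,      kind: numeric, unit: '%',     healthy: [1.0, 6.0],   extreme: [0.05, 50.0]}
  - {name: lymphocytes_pct,      kind: numeric, unit: '%',     healthy: [20, 45],     extreme: [1, 95]}
  - {name: monocytes_pct,        kind: numeric, unit: '%',     healthy: [2, 10],      extreme: [0.2, 60]}
  - {name: mcv,                  kind: numeric, unit: fL,      healthy: [80, 100],    extreme: [50, 140]}
  - {name: hemoglobin,           kind: numeric, unit: g/dL,    healthy: [12.0, 17.5], extreme: [3.0, 22.0]}
  - {name: erythrocytes,         kind: numeric, unit: 10^12/L, healthy: [4.0, 6.0],   extreme: [1.0, 9.0]}
  - {name: mch,                  kind: numeric, unit: pg,      healthy: [27, 33],     extreme: [15, 45]}
  - {name: mchc,                 kind: numeric, unit: g/dL,    healthy: [32, 36],     extreme: [22, 42]}
  - {name: rdw_cv,               kind: numeric, unit: '%',     healthy: [11.5, 14.5], extreme: [9.0, 35.0]}
  - {name: rdw_sd,               kind: numeric, unit: fL,      healthy: [39, 46],     extreme: [25, 90]}
  - {name: hematocrit,           kind: numeric, unit: '%',     healthy: [36, 52],     extreme: [10, 70]}
  - {name: platelets,            kind: numeric, unit: 10^9/L,  healthy: [150, 400],   extreme: [5, 1500]}
  # ---- 12 qualitative variables ----------------------------------------
  - name: environment
    kind: qualitative
    categories: [rural, urban]
    benign: [rural]
  - name: tumor_position
    kind: qualitative
    categories: [none, cecum, ascending, transverse, descending, sigmoid, rectum]
    benign: [none]
  - name: t_stage
    kind: qualitative
    categories: [T0, T1, T2, T3, T4]
    benign: [T0]
  - name: n_stage
    kind: qualitative
    categories: [N0, N1, N2]
    benign: [N0]
  - name: m_stage
    kind: qualitative
    categories: [M0, M1]
    benign: [M0]
  - name: dukes
    kind: qualitative
    categories: [none, A, B, C, D]
    benign: [none]
  - name: pathology
    # Category "1" = no associated pathology that could influence tumor
    # growth; categories 2-10 code increasing numbers of associated diseases.
    kind: qualitative
    categories: ['1', '2', '3', '4', '5', '6', '7', '8', '9', '10']
    benign: ['1']
  - name: technical_approach
    kind: qualitative
    categories: [none, laparoscopic, open, converted]
    benign: [none]
  - name: complications
    kind: qualitative
    categories: [none, minor, major]
    benign: [none]
  - name: incidents
    kind: qualitative
    categories: [none, present]
    benign: [none]
  - name: usg_dimensions
    kind: qualitative
    categories: [normal, small, medium, large]
    benign: [normal]
  - name: usg_localization
    kind: qualitative
    categories: [none, right_colon, left_colon, rectum]
    benign: [none]
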