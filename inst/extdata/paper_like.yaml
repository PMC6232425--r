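# Simulation scenario mirroring a compounded-disturbance microcosm study:
# one undisturbed control, three repeated single disturbances (freeze-thaw F,
# heat H, anoxia A) and the six orderings of the three disturbances, with
# 4 replicate microcosms destructively sampled at T0 (pre-disturbance) to T4.
# Per-variable true standardized effects (delta, Hedges'-g scale, applied to
# all 26 variables of a cell) follow the qualitative patterns reported for
# such experiments: resilience after freeze-thaw, persistent impact of heat,
# delayed impact of anoxia, and chronology-dependent aggregate impact that
# is strongest for sequences starting with anoxia.
mode: simulate
control: control
seed: 20201
rarefaction_depth: 2200
unifrac: weighted_unifrac
permutations: 999
eai_timepoints: [T1, T2, T3, T4]

simulate:
  n_replicates: 4
  n_otus: 300
  depth_range: [2500, 6000]
  effects:
    - {treatment: F, timepoint: T1, delta: 1.40}
    - {treatment: F, timepoint: T2, delta: 1.40}
    - {treatment: F, timepoint: T3, delta: 1.00}
    - {treatment: F, timepoint: T4, delta: 0.65}
    - {treatment: H, timepoint: T1, delta: 1.50}
    - {treatment: H, timepoint: T2, delta: 1.60}
    - {treatment: H, timepoint: T3, delta: 1.90}
    - {treatment: H, timepoint: T4, delta: 1.75}
    - {treatment: A, timepoint: T1, delta: 0.70}
    - {treatment: A, timepoint: T2, delta: 1.00}
    - {treatment: A, timepoint: T3, delta: 0.65}
    - {treatment: A, timepoint: T4, delta: 2.00}
    - {treatment: [FHA, FAH, HFA, HAF, AFH, AHF], timepoint: [T1, T2], delta: 0.90}
    - {treatment: FHA, timepoint: T3, delta: 1.30}
    - {treatment: FAH, timepoint: T3, delta: 1.10}
    - {treatment: HFA, timepoint: T3, delta: 1.15}
    - {treatment: HAF, timepoint: T3, delta: 0.85}
    - {treatment: AFH, timepoint: T3, delta: 1.35}
    - {treatment: AHF, timepoint: T3, delta: 1.80}
    - {treatment: FHA, timepoint: T4, delta: 1.50}
    - {treatment: FAH, timepoint: T4, delta: 1.00}
    - {treatment: HFA, timepoint: T4, delta: 1.30}
    - {treatment: HAF, timepoint: T4, delta: 1.20}
    - {treatment: AFH, timepoint: T4, delta: 2.50}
    - {treatment: AHF, timepoint: T4, delta: 2.20}
  shifts:
    - {treatment: [F, H, A], timepoint: [T1, T2, T3, T4], fraction: 0.3, log_fold: 0.5}
    - {treatment: [FHA, FAH, HFA, HAF], timepoint: [T3, T4], fraction: 0.3, log_fold: 0.5}
    - {treatment: [AFH, AHF], timepoint: [T3, T4], fraction: 0.3, log_fold: 0.8}

varpart:
  predictors: [weighted_unifrac, PNA, qnosZI_16S, qnosZII, qnirK, qnirK_16S,
               faith_pd, simpson_reciprocal]
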