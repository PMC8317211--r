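# Default pipeline configuration for the synthetic four-dataset study.
# Every statistical parameter of the analysis appears here explicitly.

out_dir: tmtde_out
seed: 1
n_proteins: 300

test:
  s0: 0.5              # moderation constant of the d-statistic (log2 scale)
  fdr: 0.05            # permutation-FDR significance level
  n_permutations: 250  # requested label randomizations (exhaustive when fewer exist)
  anova_fdr: 0.05      # BH level of the four-group ANOVA prefilter
  anova_enabled: true  # per-dataset override comes from the dataset plan

min_score: 0.7         # minimum combined interaction score for network edges

mcode:
  node_score_cutoff: 0.2
  degree_cutoff: 4
  k_core: 4
  max_depth: 100
  haircut: true
  fluff: false

synth:
  n_proteins: 300
  n_plexes: 2          # two TMT 10-plex runs
  reps_per_group: 2    # 2 replicates/group/plex -> n = 4 per group
  frac_sex_de: 0.10
  frac_trt_de_f: 0.10
  frac_trt_de_m: 0.10
  effect_size_log2: 1.0
  effect_sd_log2: 0.25
  sigma_within: 0.25   # within-group biological + technical log2 sd
  sigma_pool: 0.05     # technical log2 sd of pooled reference channels
  base_mean_log2: 20
  base_sd_log2: 1.5
  loading_sd_log2: 0.25
  batch_sd_log2: 0.40
  frac_decoy: 0.03
  frac_contaminant: 0.03
  frac_missing: 0.01
  seed: 1
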