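# Shared fixtures, built in code at test time.

# small complete paired study on the raw scale
small_study <- function(n_metabolites = 30, n1 = 8, n2 = 7, seed = 101,
                        de_fraction = 0.2, effect_size = 1,
                        profile = correlation_profile("high")) {
  generate_paired_study(group_design(n1, n2, de_fraction, effect_size),
                        profile, n_metabolites, seed = seed)
}

# log-scale matrix with left-censoring-weighted missingness
masked_log_matrix <- function(n_metabolites = 50, n_subjects = 30, p = 30,
                              seed = 202) {
  st <- generate_paired_study(group_design(n_subjects %/% 2,
                                           n_subjects - n_subjects %/% 2,
                                           0, 0),
                              correlation_profile("high"), n_metabolites,
                              seed = seed)
  mask <- induce_missingness(st$A, p, seed = seed + 1)
  list(complete = log_transform(st$A),
       masked = log_transform(apply_mask(st$A, mask)),
       mask = mask)
}

# fast settings for unit tests (fewer trees than the 100-tree default)
fast_settings <- function(seed = 1, ...) {
  imputer_settings(rf_trees = 30, seed = seed, ...)
}
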