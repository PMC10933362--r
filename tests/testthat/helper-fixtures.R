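# Shared fixture builders. Everything is generated in code; no data files.

# random strictly positive 11-part concentration vector summing well below kappa
random_concentrations <- function(seed) {
  set.seed(seed)
  conc <- exp(rnorm(11, mean = log(c(30, 4, 25, 10, 3, 7, 0.04, 0.03, 0.06,
                                     0.1, 0.06)), sd = 0.3))
  setNames(conc, onion_parts())
}

random_composition <- function(seed, kappa = 1000) {
  close_composition(random_concentrations(seed), kappa = kappa)
}

random_clr <- function(seed) clr_transform(random_composition(seed))

# bare feature_matrix around a numeric matrix, for model-level tests
make_fm <- function(x, y, strata = rep("all", nrow(x)),
                    categorical = character(0)) {
  structure(list(x = x, missing_mask = is.na(x), target = y, strata = strata,
                 codebook = list(), categorical = categorical, groups = "x"),
            class = "feature_matrix")
}

# small complete observation table via the generator (no missingness)
small_trials <- function(seed = 5, plots = 20, missing_rate = 0) {
  cfg <- generator_config(seed = seed,
                          n_trials = c(N = 4L, K = 1L, P = 1L),
                          plots_per_trial = plots,
                          missing_rate = missing_rate)
  generate_trials(cfg)
}
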