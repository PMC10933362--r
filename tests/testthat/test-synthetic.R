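test_that("default configuration reproduces the trial-set dimensions", {
  cfg <- generator_config(seed = 31)
  ts <- generate_trials(cfg)
  obs <- ts$observations
  expect_equal(length(unique(obs$trial_id)), 34)          # 26 N + 5 K + 3 P
  expect_lt(abs(nrow(obs) - 1182) / 1182, 0.05)
  feat <- setdiff(names(obs), c("trial_id", "yield"))
  expect_equal(mean(is.na(obs[feat])), 0.13, tolerance = 0.015)
  expect_false(any(is.na(obs$yield)))
  expect_true(all(obs$yield >= 0))
  expect_identical(ts$truth, cfg)                          # truth kept verbatim
  # dose gradients span the reported ranges
  expect_equal(range(obs$n_dose[grepl("_N$", obs$trial_id)], na.rm = TRUE),
               c(0, 370))
  expect_equal(max(obs$k_dose[grepl("_K$", obs$trial_id)], na.rm = TRUE), 667)
  expect_equal(max(obs$p_dose[grepl("_P$", obs$trial_id)], na.rm = TRUE), 349)
})

test_that("generation is deterministic and respects missing_rate = 0", {
  a <- generate_trials(generator_config(seed = 33))
  b <- generate_trials(generator_config(seed = 33))
  expect_identical(a$observations, b$observations)
  c0 <- generate_trials(generator_config(seed = 33, missing_rate = 0))
  expect_false(anyNA(c0$observations))
  expect_error(generator_config(plots_per_trial = 3, dose_levels = 5),
               "config error")
})

test_that("tissue draws are valid compositions centered on the cultivar ionome", {
  cfg <- generator_config(seed = 35)
  tis <- generate_tissue("Caeté", 2000, cfg, seed = 603)
  for (c_ in tis[1:25]) {
    p <- composition_parts(c_)
    expect_true(all(p > 0))
    expect_equal(sum(p), 1000, tolerance = 1e-9)
  }
  m <- do.call(rbind, lapply(tis, function(c_) unclass(clr_transform(c_))))
  ctr <- cfg$clr_centers[["Caeté"]]; ctr <- ctr - mean(ctr)
  se <- apply(m, 2, sd) / sqrt(nrow(m))
  expect_true(all(abs(colMeans(m) - ctr) < 3.5 * se))
  # vanishing spread collapses on the centroid
  tight <- generate_tissue("Omega", 5,
                           generator_config(seed = 1, clr_sd = 1e-9), seed = 2)
  ctr_o <- cfg$clr_centers[["Omega"]]
  truth <- composition_parts(suppressWarnings(clr_back_transform(ctr_o)))
  for (c_ in tight)
    expect_equal(composition_parts(c_), truth, tolerance = 1e-6)
  expect_error(generate_tissue("Nope", 3, cfg), "unknown cultivar")
})

test_that("yield follows the quadratic-plateau response", {
  cfg <- generator_config(seed = 36)
  expect_equal(quadratic_plateau(0, 220), 0)
  expect_equal(quadratic_plateau(220, 220), 1)
  expect_equal(quadratic_plateau(400, 220), 1)
  d <- seq(0, 370, by = 10)
  qp <- quadratic_plateau(d, 220)
  expect_true(all(diff(qp) >= 0))
  expect_true(all(qp[d >= 220] == 1))

  feats <- data.frame(cultivar = "Mulata", n_dose = c(0, 220, 370))
  for (nm in names(cfg$soil_coefs)) feats[[nm]] <- cfg$soil_means[[nm]]
  y <- generate_yield(feats, cfg, noise = FALSE)
  expect_equal(y[1], cfg$intercepts[["Mulata"]] * 1000)
  expect_equal(y[2], (cfg$intercepts[["Mulata"]] + cfg$plateau_gain) * 1000)
  expect_equal(y[2], y[3])
})

test_that("generated weather produces in-range climate indices", {
  cfg <- generator_config(seed = 37)
  wx <- generate_weather(150, cfg, seed = 38)
  expect_length(wx$rain, 150)
  expect_true(all(wx$rain >= 0))
  expect_true(all(wx$tmin <= wx$tmax))
  s <- sdi(wx$rain)
  expect_true(s > 0 && s < 1)
  expect_identical(wx, generate_weather(150, cfg, seed = 38))
  # concentrating all rain on one day drives SDI to its lower limit
  one_day <- c(sum(wx$rain), rep(0, 149))
  expect_equal(sdi(one_day), 0)
  # near-uniform rain drives SDI towards 1
  expect_gt(sdi(rep(10, 150) + rnorm(150, 0, 1e-6)), 0.999)
})
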