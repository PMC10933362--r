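#' Configuration of the synthetic multi-environment trial generator
#'
#' The generator emulates the statistical structure of a multi-year onion
#' fertilizer-trial database from southern Brazil: 26 N trials, 5 K trials and
#' 3 P trials of `plots_per_trial` plots each (~1182 observations at the
#' defaults), four cultivars whose tissue ionomes are logistic-normal
#' (Gaussian in clr space) around the published cultivar centroids, a
#' quadratic-plateau marketable-yield response dominated by the split-N
#' dosage, secondary linear effects of soil S and micronutrient tests, daily
#' rainfall from a dry-day/gamma mixture, and 13% of feature cells missing
#' completely at random. Underfertilized plots have their tissue N clr shifted
#' downward in proportion to the squared relative dose deficit, so nutritional
#' imbalance, tissue composition and yield are mutually consistent — the
#' planted structure that balance classification and standards recovery are
#' exercised against.
#'
#' @param seed master seed.
#' @param n_trials named counts of trials varying each nutrient
#'   (default `c(N = 26, K = 5, P = 3)`).
#' @param plots_per_trial plots per trial (default 35; must be >= `dose_levels`).
#' @param dose_levels number of dose levels per trial (default 5).
#' @param dose_max maximum dose per varied nutrient, kg/ha
#'   (default `c(N = 370, K = 667, P = 349)`).
#' @param fixed_dose dose applied when a nutrient is not the varied one, kg/ha
#'   (state-recommendation levels; default `c(N = 220, P = 100, K = 150)`).
#' @param clr_sd specimen-to-specimen SD of clr parts (default 0.15).
#' @param deficiency_shift named vector of downward clr shifts at zero N, clr
#'   units (default `c(N = 1.2, S = 0.5, K = 0.3)`), scaled by the squared
#'   relative dose deficit. S and K co-shift with N because the N sources
#'   include ammonium sulfate and K is split-applied together with the N, so
#'   underfertilized plots are depleted in all three.
#' @param intercepts cultivar base yields at zero N response, Mg/ha.
#' @param plateau_gain yield gain from zero N to the plateau, Mg/ha
#'   (default 30).
#' @param n_optimum N dose reaching the plateau, kg/ha (default 220, within
#'   the range reported for the region's Cambisols).
#' @param noise_sd plot-level yield noise SD, Mg/ha (default 2).
#' @param soil_coefs linear yield effects of standardised soil tests, Mg/ha
#'   per SD.
#' @param soil_tissue_coupling optional clr shift of tissue S, B, Zn, Mn and
#'   Fe per SD of the matching soil test (default 0: tissue and soil draws are
#'   independent). A positive value makes leaf levels track soil supply, at
#'   the cost of a selection effect on the tissue S/micronutrient means of
#'   high-yield specimens.
#' @param missing_rate MCAR missingness over feature cells (default 0.13).
#' @param season_length growing-season length, days (default 150).
#' @param dry_day_prob,rain_shape,rain_scale rainfall process: probability of
#'   a dry day, and gamma shape/scale (mm) of wet-day rain.
#' @return object of class `generator_config` (a list; also stored as `truth`
#'   with generated data for recovery tests).
#' @export
generator_config <- function(seed = 42L,
                             n_trials = c(N = 26L, K = 5L, P = 3L),
                             plots_per_trial = 35L,
                             dose_levels = 5L,
                             dose_max = c(N = 370, K = 667, P = 349),
                             fixed_dose = c(N = 220, P = 100, K = 150),
                             clr_sd = 0.15,
                             deficiency_shift = c(N = 1.2, S = 0.5, K = 0.3),
                             intercepts = c("Caeté" = 27, "Mulata" = 29,
                                            "Omega" = 28, "SCS373 Valessul" = 26),
                             plateau_gain = 30,
                             n_optimum = 220,
                             noise_sd = 2,
                             soil_coefs = c(soil_s = 0.8, soil_b = 0.4,
                                            soil_zn = 0.4, soil_mn = 0.3,
                                            soil_fe = 0.25),
                             soil_tissue_coupling = 0,
                             missing_rate = 0.13,
                             season_length = 150L,
                             dry_day_prob = 0.45,
                             rain_shape = 0.8,
                             rain_scale = 12) {
  stopifnot(clr_sd > 0, noise_sd > 0, missing_rate >= 0, missing_rate < 0.5,
            all(dose_max >= 0), all(fixed_dose >= 0), n_optimum > 0,
            season_length >= 30)
  if (plots_per_trial < dose_levels)
    stop("config error: plots_per_trial (", plots_per_trial,
         ") must be >= dose_levels (", dose_levels, ")")
  ref <- onion_clr_reference()
  centers <- lapply(names(intercepts), function(cv) {
    rows <- ref[ref$cultivar == cv, ]
    setNames((rows$ci_low + rows$ci_high) / 2, rows$part)
  })
  names(centers) <- names(intercepts)
  soil_means <- c(clay = 50, organic_matter = 4.5, ph_water = 5.8, soil_p = 11,
                  soil_k = 240, soil_ca = 8.5, soil_mg = 4.3, soil_s = 24,
                  soil_b = 1.0, soil_cu = 6, soil_zn = 4, soil_mn = 15,
                  soil_fe = 120)
  soil_sds <- c(clay = 12, organic_matter = 1.2, ph_water = 0.35, soil_p = 6,
                soil_k = 90, soil_ca = 2.5, soil_mg = 1.0, soil_s = 9,
                soil_b = 0.3, soil_cu = 4, soil_zn = 3, soil_mn = 9,
                soil_fe = 40)
  structure(list(seed = as.integer(seed), n_trials = n_trials,
                 plots_per_trial = as.integer(plots_per_trial),
                 dose_levels = as.integer(dose_levels), dose_max = dose_max,
                 fixed_dose = fixed_dose, clr_centers = centers,
                 clr_sd = clr_sd, deficiency_shift = deficiency_shift,
                 intercepts = intercepts, plateau_gain = plateau_gain,
                 n_optimum = n_optimum, noise_sd = noise_sd,
                 soil_coefs = soil_coefs,
                 soil_tissue_coupling = soil_tissue_coupling,
                 soil_means = soil_means,
                 soil_sds = soil_sds, missing_rate = missing_rate,
                 season_length = as.integer(season_length),
                 dry_day_prob = dry_day_prob, rain_shape = rain_shape,
                 rain_scale = rain_scale),
            class = "generator_config")
}

#' Quadratic-plateau dose response
#'
#' Relative response \eqn{1 - (1 - d/d_{opt})^2} below the optimum dose and 1
#' at or above it: non-decreasing up to the optimum and flat after, avoiding
#' the over-fertilization bias of a pure quadratic.
#'
#' @param dose nutrient dose, kg/ha (vectorised).
#' @param optimum dose reaching the plateau, kg/ha.
#' @return relative response in `[0, 1]`.
#' @export
quadratic_plateau <- function(dose, optimum) {
  stopifnot(optimum > 0, all(dose >= 0))
  ifelse(dose >= optimum, 1, 1 - (1 - dose / optimum)^2)
}

tissue_clr_draw <- function(center, n, clr_sd, seed) {
  set.seed(seed)
  m <- matrix(rnorm(n * length(center), mean = rep(center, each = n),
                    sd = clr_sd), nrow = n)
  m <- m - rowMeans(m)           # project onto the sum-zero clr subspace
  colnames(m) <- names(center)
  m
}

#' Generate tissue compositions for a cultivar
#'
#' Logistic-normal ionome model: clr vectors are drawn from a Gaussian
#' centered on the cultivar's clr center (optionally shifted, e.g. for
#' nutrient deficiency), projected onto the sum-zero subspace, and
#' back-transformed to concentrations closed at 1000 g/kg.
#'
#' @param cultivar cultivar name present in `config$clr_centers`.
#' @param n number of specimens.
#' @param config a [generator_config()].
#' @param seed integer seed.
#' @param shift optional numeric shift added to the clr center (recycled over
#'   parts; named entries are applied to the matching parts).
#' @return list of `composition` objects.
#' @export
generate_tissue <- function(cultivar, n, config = generator_config(),
                            seed = config$seed, shift = NULL) {
  center <- config$clr_centers[[cultivar]]
  if (is.null(center))
    stop("config error: unknown cultivar '", cultivar, "'; available: ",
         paste(names(config$clr_centers), collapse = ", "))
  if (!is.null(shift)) {
    if (!is.null(names(shift))) {
      center[names(shift)] <- center[names(shift)] + shift
    } else center <- center + shift
  }
  m <- tissue_clr_draw(center, n, config$clr_sd, seed)
  lapply(seq_len(n), function(i)
    clr_back_transform(setNames(m[i, ], colnames(m)), kappa = 1000))
}

#' Generate daily weather for one growing season
#'
#' Daily rainfall is a dry-day/gamma mixture; daily temperatures follow a
#' seasonal sinusoid with noise, with tmin below tmax by a positive diurnal
#' range. The rainfall SDI of a default season lies strictly inside (0, 1).
#'
#' @param season_length days (>= 30).
#' @param config a [generator_config()].
#' @param seed integer seed.
#' @return list with numeric vectors `rain` (mm), `tmin`, `tmax` (°C).
#' @export
generate_weather <- function(season_length = 150L, config = generator_config(),
                             seed = config$seed) {
  stopifnot(season_length >= 30)
  set.seed(seed)
  wet <- rbinom(season_length, 1, 1 - config$dry_day_prob)
  rain <- wet * rgamma(season_length, shape = config$rain_shape,
                       scale = config$rain_scale)
  day <- seq_len(season_length)
  tmean <- 16 + 5 * sin(2 * pi * (day / 365) + runif(1, 0, 2 * pi)) +
    rnorm(season_length, 0, 1.5)
  range_ <- pmax(2, rnorm(season_length, 9, 1.5))
  list(rain = rain, tmin = tmean - range_ / 2, tmax = tmean + range_ / 2)
}

#' Generate plot-level marketable yield
#'
#' Yield (kg/ha) = cultivar intercept + plateau_gain × quadratic-plateau
#' response to the split-N dose + linear effects of standardised soil S and
#' micronutrient tests + Gaussian noise, truncated at zero.
#'
#' @param features data.frame with columns `cultivar`, `n_dose` and the soil
#'   test columns named in `config$soil_coefs`.
#' @param config a [generator_config()].
#' @param seed integer seed (set `noise = FALSE` for the deterministic part).
#' @param noise include plot noise (default TRUE).
#' @return numeric vector of yields, kg/ha.
#' @export
generate_yield <- function(features, config = generator_config(),
                           seed = config$seed, noise = TRUE) {
  stopifnot(all(c("cultivar", "n_dose") %in% names(features)))
  mg <- config$intercepts[as.character(features$cultivar)] +
    config$plateau_gain * quadratic_plateau(features$n_dose, config$n_optimum)
  for (nm in names(config$soil_coefs)) {
    z <- (features[[nm]] - config$soil_means[[nm]]) / config$soil_sds[[nm]]
    mg <- mg + config$soil_coefs[[nm]] * z
  }
  if (noise) {
    set.seed(seed)
    mg <- mg + rnorm(nrow(features), 0, config$noise_sd)
  }
  pmax(0, unname(mg) * 1000)
}

#' Generate a synthetic multi-environment trial set
#'
#' Builds the full observation table: per trial a municipality, year,
#' cultivar, establishment method (transplanting in Ituporanga/Atalanta,
#' direct seeding in Caçador/Lebon Régis), tillage, previous crop, one soil
#' test (composited per trial), one season of daily weather summarised into
#' climate features, and `plots_per_trial` plots over an evenly spaced dose
#' gradient of the trial's varied nutrient (N 0–370, K 0–667, P 0–349 kg/ha;
#' non-varied nutrients fixed at recommendation levels). Tissue compositions
#' and yields follow the planted response model, then `missing_rate` of the
#' feature cells (never the yield) are blanked completely at random.
#'
#' @param config a [generator_config()].
#' @return object of class `synthetic_trials`: `observations` (data.frame)
#'   and `truth` (the generating config, verbatim).
#' @export
generate_trials <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  munis <- c("Ituporanga", "Atalanta", "Caçador", "Lebon Régis")
  prev <- c("black oat", "millet", "sweet potato", "tobacco", "corn",
            "cowpea", "velvet bean")
  cultivars <- names(config$clr_centers)
  varied <- rep(names(config$n_trials), config$n_trials)
  n_tr <- length(varied)
  rows <- vector("list", n_tr)
  set.seed(derive_seed(config$seed, "trial-layout"))
  tr_muni <- sample(munis, n_tr, replace = TRUE)
  tr_year <- sample(2007:2020, n_tr, replace = TRUE)
  tr_cv <- sample(rep(cultivars, length.out = n_tr))  # balanced over trials
  tr_till <- sample(c("conventional", "no-till"), n_tr, replace = TRUE)
  tr_prev <- sample(prev, n_tr, replace = TRUE)
  tr_doy <- sample(100:200, n_tr, replace = TRUE)

  for (t in seq_len(n_tr)) {
    npl <- config$plots_per_trial
    nut <- varied[t]
    set.seed(derive_seed(config$seed, paste0("soil", t)))
    soil <- pmax(config$soil_means * 0.05,
                 rnorm(length(config$soil_means), config$soil_means,
                       config$soil_sds))
    names(soil) <- names(config$soil_means)
    acidity <- max(0.3, rnorm(1, 1.5, 0.6))
    k_cmol <- soil[["soil_k"]] / 391   # mg/dm3 -> cmol_c/dm3
    cb <- cec_and_base_saturation(soil[["soil_ca"]], soil[["soil_mg"]],
                                  k_cmol, acidity)
    wx <- generate_weather(config$season_length, config,
                           derive_seed(config$seed, paste0("weather", t)))
    est <- if (tr_muni[t] %in% c("Ituporanga", "Atalanta"))
      "transplant" else "direct-seed"

    levels_ <- seq(0, config$dose_max[[nut]], length.out = config$dose_levels)
    dose <- rep(levels_, length.out = npl)
    doses <- list(N = rep(config$fixed_dose[["N"]], npl),
                  P = rep(config$fixed_dose[["P"]], npl),
                  K = rep(config$fixed_dose[["K"]], npl))
    doses[[nut]] <- dose

    deficit <- (1 - pmin(doses$N, config$n_optimum) / config$n_optimum)^2
    center <- config$clr_centers[[tr_cv[t]]]
    cm <- matrix(rep(center, each = npl), nrow = npl,
                 dimnames = list(NULL, names(center)))
    for (part in names(config$deficiency_shift))
      cm[, part] <- cm[, part] - config$deficiency_shift[[part]] * deficit
    soil_map <- c(S = "soil_s", B = "soil_b", Zn = "soil_zn", Mn = "soil_mn",
                  Fe = "soil_fe")
    for (part in names(soil_map)) {
      z <- (soil[[soil_map[[part]]]] - config$soil_means[[soil_map[[part]]]]) /
        config$soil_sds[[soil_map[[part]]]]
      cm[, part] <- cm[, part] + config$soil_tissue_coupling * z
    }
    set.seed(derive_seed(config$seed, paste0("tissue", t)))
    clrm <- cm + matrix(rnorm(npl * ncol(cm), 0, config$clr_sd), npl)
    clrm <- clrm - rowMeans(clrm)
    conc <- t(apply(clrm, 1, function(v) {
      e <- exp(v - max(v)); 1000 * e / sum(e)
    }))
    colnames(conc) <- paste0("tissue_", tolower(colnames(cm)))

    df <- data.frame(
      trial_id = sprintf("T%02d_%s", t, nut),
      year = tr_year[t], municipality = tr_muni[t], cultivar = tr_cv[t],
      establishment = est, tillage = tr_till[t], previous_crop = tr_prev[t],
      n_dose = doses$N, p_dose = doses$P, k_dose = doses$K,
      n_splits = if (est == "transplant") 3L else 4L,
      clay = soil[["clay"]], organic_matter = soil[["organic_matter"]],
      ph_water = soil[["ph_water"]], soil_p = soil[["soil_p"]],
      soil_k = soil[["soil_k"]], soil_ca = soil[["soil_ca"]],
      soil_mg = soil[["soil_mg"]], soil_s = soil[["soil_s"]],
      soil_b = soil[["soil_b"]], soil_cu = soil[["soil_cu"]],
      soil_zn = soil[["soil_zn"]], soil_mn = soil[["soil_mn"]],
      soil_fe = soil[["soil_fe"]],
      cec = cb$cec, base_saturation = cb$base_saturation,
      sdi = sdi(wx$rain), degree_days = degree_days(wx$tmin, wx$tmax),
      season_length = config$season_length,
      tmin = min(wx$tmin), tmax = max(wx$tmax),
      precipitation = sum(wx$rain), planting_doy = tr_doy[t],
      stringsAsFactors = FALSE
    )
    df <- cbind(df, as.data.frame(conc)[seq_len(ncol(conc) - 1)])  # drop tissue_fv
    df$yield <- generate_yield(df, config,
                               derive_seed(config$seed, paste0("yield", t)))
    rows[[t]] <- df
  }
  obs <- do.call(rbind, rows)
  rownames(obs) <- NULL

  if (config$missing_rate > 0) {
    feat_cols <- setdiff(names(obs), c("trial_id", "yield"))
    set.seed(derive_seed(config$seed, "missing"))
    for (cl in feat_cols) {
      hit <- runif(nrow(obs)) < config$missing_rate
      obs[[cl]][hit] <- NA
    }
  }
  structure(list(observations = obs, truth = config),
            class = "synthetic_trials")
}

#' @export
print.synthetic_trials <- function(x, ...) {
  cat("synthetic_trials:", nrow(x$observations), "observations,",
      length(unique(x$observations$trial_id)), "trials,",
      sprintf("%.1f%% missing feature cells\n",
              100 * mean(is.na(x$observations[setdiff(names(x$observations),
                                                      c("trial_id", "yield"))]))))
  invisible(x)
}
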