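#' Run a configured analysis stage
#'
#' Config-driven entry point wiring the package's stages together. The config
#' (YAML file or list) names a `command` and its inputs/outputs; one master
#' seed deterministically derives per-stage seeds (stage-name hashing) so
#' stages can be re-run independently yet reproducibly. Every run writes its
#' tabular outputs as delimited text plus a `manifest.yml` recording the
#' command, resolved config, seed and package version. The same config and
#' seed produce byte-identical tables.
#'
#' Commands:
#' \describe{
#'   \item{generate}{write a synthetic observation table (`observations.csv`)
#'     and the generating truth (`truth.yml`).}
#'   \item{rank}{assemble + impute features, write RReliefF and gain-ratio
#'     relevance tables.}
#'   \item{regress}{repeated stratified yield regression; write averaged and
#'     per-repeat metrics.}
#'   \item{classify}{balance classification at the yield cutoff; write
#'     metrics and per-specimen quadrants.}
#'   \item{standards}{classify, select TN specimens, derive standards and
#'     concentration quartiles; write both tables.}
#'   \item{diagnose}{diagnose specimens in `input` against a standards file.}
#' }
#'
#' @param config path to a YAML config file, or an equivalent named list.
#'   Recognised top-level keys: `command`, `input` (path to an observation
#'   table for read commands), `out_dir`, `seed`, plus optional `generator`
#'   and `model` blocks whose keys mirror [generator_config()] and
#'   [model_config()], and `features` (list with `groups`, `exclude`,
#'   `clr_tissue`).
#' @param seed optional master seed overriding the config's.
#' @param out_dir optional output directory overriding the config's.
#' @return (invisibly) a list with the written file paths and the stage's
#'   in-memory result.
#' @export
run_config <- function(config, seed = NULL, out_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg)) stop("config error: config must be a file path or list")
  cmds <- c("generate", "rank", "regress", "classify", "standards", "diagnose")
  if (is.null(cfg$command) || !cfg$command %in% cmds)
    stop("config error at 'command': must be one of ",
         paste(cmds, collapse = ", "))
  if (!is.null(seed)) cfg$seed <- seed
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  if (is.null(cfg$out_dir)) stop("config error at 'out_dir': required")
  reads <- setdiff(cmds, "generate")
  if (cfg$command %in% reads) {
    if (is.null(cfg$input)) stop("config error at 'input': required for ",
                                 cfg$command)
    if (!file.exists(cfg$input)) stop("config error at 'input': file not found: ",
                                      cfg$input)
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  gen_cfg <- function() do.call(generator_config,
                                c(list(seed = derive_seed(cfg$seed, "generate")),
                                  cfg$generator))
  mod_cfg <- function(stage) {
    args <- cfg$model
    args$seed <- derive_seed(cfg$seed, stage)
    do.call(model_config, if (is.null(args)) list(seed = derive_seed(cfg$seed, stage)) else args)
  }
  feats <- function(obs, defaults = names(feature_groups())) {
    f <- cfg$features
    assemble_features(obs,
                      groups = if (is.null(f$groups)) defaults else unlist(f$groups),
                      exclude = unlist(f$exclude))
  }
  # impute on the full raw feature set once; clr conversion happens after
  load_imputed <- function(groups) {
    obs <- read_observations(cfg$input)
    fm <- feats(obs, groups)
    if (any(fm$missing_mask))
      fm <- impute_features(fm, seed = derive_seed(cfg$seed, "impute"))
    list(obs = obs, fm = fm)
  }
  classification_features <- function(fm) {
    fmc <- select_features(fm, intersect(c("cultivar",
                                           grep("^tissue_", colnames(fm$x), value = TRUE)),
                                         colnames(fm$x)))
    if (isTRUE(cfg$features$clr_tissue)) fmc <- with_clr_tissue(fmc)
    fmc
  }
  p <- function(...) file.path(cfg$out_dir, paste0(...))
  written <- character(0)
  result <- switch(cfg$command,
    generate = {
      ts <- generate_trials(gen_cfg())
      write_observations(ts$observations, p("observations.csv"))
      truth <- ts$truth
      truth$clr_centers <- lapply(truth$clr_centers, as.list)
      yaml::write_yaml(lapply(truth, function(v)
        if (is.numeric(v) && !is.null(names(v))) as.list(v) else v),
        p("truth.yml"))
      written <- c(p("observations.csv"), p("truth.yml"))
      ts
    },
    rank = {
      li <- load_imputed(names(feature_groups()))
      if (isTRUE(cfg$features$clr_tissue)) li$fm <- with_clr_tissue(li$fm)
      rr <- rrelieff(li$fm, seed = derive_seed(cfg$seed, "rrelieff"))
      cutoff <- if (is.null(cfg$model$yield_cutoff)) 50 else cfg$model$yield_cutoff
      gr <- gain_ratio(li$fm, li$fm$target > cutoff * 1000)
      write_relevance(rr, p("rrelieff.csv"))
      write_relevance(gr, p("gain_ratio.csv"))
      written <- c(p("rrelieff.csv"), p("gain_ratio.csv"))
      list(rrelieff = rr, gain_ratio = gr)
    },
    regress = {
      li <- load_imputed(names(feature_groups()))
      rep_ <- evaluate_regression(li$fm, mod_cfg("regress"))
      write_model_report(rep_, p("regression.csv"))
      written <- p("regression.csv")
      rep_
    },
    classify = {
      li <- load_imputed(names(feature_groups()))
      rep_ <- classify_balance(classification_features(li$fm), mod_cfg("classify"))
      write_model_report(rep_, p("classification.csv"))
      written <- p("classification.csv")
      rep_
    },
    standards = {
      li <- load_imputed(names(feature_groups()))
      rep_ <- classify_balance(classification_features(li$fm), mod_cfg("classify"))
      imputed_obs <- decode_features(li$fm)   # has cultivar + imputed tissue
      tn <- select_true_negatives(rep_, imputed_obs)
      st <- derive_standards(tn, provenance = list(
        cutoff = rep_$cutoff, learner = rep_$config$learner,
        feature_space = if (isTRUE(cfg$features$clr_tissue)) "clr" else "raw"))
      write_standards(st, p("standards.csv"))
      qt <- concentration_quartiles(tn)
      write.csv(qt, p("quartiles.csv"), row.names = FALSE)
      written <- c(p("standards.csv"), p("quartiles.csv"))
      list(classification = rep_, standards = st, quartiles = qt)
    },
    diagnose = {
      if (is.null(cfg$standards) || !file.exists(cfg$standards))
        stop("config error at 'standards': standards file required")
      sdf <- read_standards(cfg$standards)
      stds <- rebuild_standards(sdf)
      obs <- read_observations(cfg$input)
      out <- do.call(rbind, lapply(seq_len(nrow(obs)), function(i) {
        conc <- setNames(as.numeric(obs[i, paste0("tissue_", tolower(onion_parts()))]),
                         onion_parts())
        d <- diagnose(close_composition(conc), stds, obs$cultivar[i],
                      index_threshold = if (is.null(cfg$index_threshold)) 1
                                        else cfg$index_threshold)
        data.frame(row = i, cultivar = obs$cultivar[i],
                   part = names(d$indices), index = as.numeric(d$indices),
                   verdict = d$verdict, row.names = NULL)
      }))
      write.csv(out, p("diagnosis.csv"), row.names = FALSE)
      written <- p("diagnosis.csv")
      out
    })
  yaml::write_yaml(list(command = cfg$command, seed = cfg$seed,
                        config = cfg[setdiff(names(cfg), c("seed", "command"))],
                        package = as.character(utils::packageVersion("oniondx")),
                        files = basename(written)),
                   p("manifest.yml"))
  invisible(list(files = c(written, p("manifest.yml")), result = result))
}

#' Rebuild a standards table from its delimited form
#'
#' @param sdf data.frame as returned by [read_standards()].
#' @return a `standards_table`.
#' @export
rebuild_standards <- function(sdf) {
  need <- c("cultivar", "part", "ci_low", "ci_high", "clr_mean", "clr_sd",
            "centroid", "n", "alpha")
  if (!all(need %in% names(sdf)))
    stop("standards file must have columns ", paste(need, collapse = ", "))
  stds <- lapply(split(sdf, sdf$cultivar), function(rows) {
    rows <- rows[match(onion_parts(with_fv = TRUE), rows$part), ]
    structure(list(cultivar = rows$cultivar[1], labels = rows$part,
                   clr_mean = setNames(rows$clr_mean, rows$part),
                   clr_sd = setNames(rows$clr_sd, rows$part),
                   ci_low = setNames(rows$ci_low, rows$part),
                   ci_high = setNames(rows$ci_high, rows$part),
                   alpha = rows$alpha[1], n = rows$n[1],
                   centroid = clr_back_transform(setNames(rows$clr_mean, rows$part)),
                   degenerate = any(rows$clr_sd == 0)),
              class = "nutrient_standard")
  })
  structure(list(standards = stds, provenance = list(source = "file")),
            class = "standards_table")
}
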