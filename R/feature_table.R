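#' Candidate feature groups of the trial observation table
#'
#' Column names of each feature group as stored in the delimited observation
#' table: climate indices, management categoricals, soil tests, tissue tests
#' (g/kg) and fertilization. Management features are categorical; everything
#' else is numeric.
#'
#' @return named list of character vectors.
#' @export
feature_groups <- function() {
  list(
    climate = c("sdi", "degree_days", "season_length", "tmin", "tmax",
                "precipitation", "planting_doy"),
    management = c("cultivar", "establishment", "tillage", "previous_crop",
                   "municipality"),
    soil = c("clay", "organic_matter", "ph_water", "soil_p", "soil_k",
             "soil_ca", "soil_mg", "soil_s", "soil_b", "soil_cu", "soil_zn",
             "soil_mn", "soil_fe", "cec", "base_saturation"),
    tissue = paste0("tissue_", tolower(onion_parts())),
    fertilization = c("n_dose", "p_dose", "k_dose", "n_splits")
  )
}

categorical_features <- function() feature_groups()$management

#' Assemble trial observations into an analyzable feature matrix
#'
#' Selects the requested feature groups from an observation table, encodes
#' categorical features as integer codes with a stored codebook (decision-tree
#' learners split on the codes natively; one-hot encoding is not used), and
#' builds the target vector and sampling strata. Column order is
#' deterministic (group order, then the group's declared order). Columns that
#' are entirely missing are dropped with a warning.
#'
#' Strata are combinations of cultivar × establishment × municipality;
#' combinations with fewer than `min_stratum` rows are collapsed into a pooled
#' stratum so every stratum can be split.
#'
#' @param observations data.frame, one row per plot-season (see
#'   [generate_trials()] / [read_observations()] for the column layout).
#' @param groups subset of `names(feature_groups())`.
#' @param target name of the target column (default `"yield"`, kg/ha).
#' @param clr_tissue if `TRUE`, tissue concentrations are replaced by their
#'   clr values (computed row-wise with the filling value at kappa = 1000).
#' @param exclude feature columns to drop after group selection (e.g.
#'   `c("p_dose", "k_dose")` for the configuration excluding P-K
#'   fertilization).
#' @param min_stratum minimum stratum size before pooling (default 4).
#' @return an object of class `feature_matrix`: list with `x` (numeric
#'   matrix), `missing_mask`, `target`, `strata`, `codebook`, `categorical`,
#'   `groups`.
#' @export
assemble_features <- function(observations, groups = names(feature_groups()),
                              target = "yield", clr_tissue = FALSE,
                              exclude = NULL, min_stratum = 4L) {
  stopifnot(is.data.frame(observations), nrow(observations) > 0L)
  fg <- feature_groups()
  unknown <- setdiff(groups, names(fg))
  if (length(unknown) > 0L)
    stop("configuration error: unknown feature group(s) ",
         paste(unknown, collapse = ", "))
  obs <- observations
  if (clr_tissue && "tissue" %in% groups) {
    tis <- fg$tissue
    avail <- intersect(tis, names(obs))
    clrm <- matrix(NA_real_, nrow(obs), length(onion_parts(with_fv = TRUE)),
                   dimnames = list(NULL, paste0("clr_", tolower(onion_parts(with_fv = TRUE)))))
    tm <- as.matrix(obs[avail])
    complete <- rowSums(is.na(tm)) == 0
    for (i in which(complete)) {
      conc <- setNames(as.numeric(tm[i, ]), onion_parts()[match(avail, fg$tissue)])
      cv <- tryCatch(clr_transform(close_composition(conc)), error = function(e) NULL)
      if (!is.null(cv)) clrm[i, ] <- unclass(cv)
    }
    obs <- cbind(obs[setdiff(names(obs), avail)], as.data.frame(clrm))
    fg$tissue <- colnames(clrm)
  }
  cols <- unlist(fg[groups], use.names = FALSE)
  cols <- setdiff(intersect(cols, names(obs)), exclude)
  if (length(cols) == 0L) stop("configuration error: no feature columns selected")

  codebook <- list()
  x <- matrix(NA_real_, nrow(obs), length(cols), dimnames = list(NULL, cols))
  for (cl in cols) {
    v <- obs[[cl]]
    if (cl %in% categorical_features() || is.character(v) || is.factor(v)) {
      lev <- sort(unique(as.character(v[!is.na(v)])))
      codebook[[cl]] <- lev
      x[, cl] <- as.numeric(match(as.character(v), lev))
    } else {
      x[, cl] <- as.numeric(v)
    }
  }
  all_na <- colSums(!is.na(x)) == 0
  if (any(all_na)) {
    warning("dropping all-missing column(s): ",
            paste(cols[all_na], collapse = ", "))
    x <- x[, !all_na, drop = FALSE]
    codebook <- codebook[intersect(names(codebook), colnames(x))]
  }

  y <- if (!is.null(target) && target %in% names(observations))
    as.numeric(observations[[target]]) else NULL

  skey <- intersect(c("cultivar", "establishment", "municipality"),
                    names(observations))
  strata <- if (length(skey) > 0L)
    do.call(paste, c(lapply(observations[skey], as.character), sep = "|"))
  else rep("all", nrow(observations))
  tab <- table(strata)
  small <- names(tab)[tab < min_stratum]
  if (length(small) > 0L) strata[strata %in% small] <- "(pooled)"

  structure(list(x = x, missing_mask = is.na(x), target = y, strata = strata,
                 codebook = codebook,
                 categorical = intersect(names(codebook), colnames(x)),
                 groups = groups),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("feature_matrix:", nrow(x$x), "rows x", ncol(x$x), "features (",
      paste(x$groups, collapse = ", "), ")\n")
  cat("  missing cells:", sum(x$missing_mask), sprintf("(%.1f%%)\n",
      100 * mean(x$missing_mask)))
  cat("  strata:", length(unique(x$strata)), " target:",
      if (is.null(x$target)) "none" else "present", "\n")
  invisible(x)
}

#' Decode a feature matrix back to labelled columns
#'
#' Inverse of the integer encoding applied by [assemble_features()]; numeric
#' columns are passed through, categorical codes are mapped back to their
#' levels via the codebook (round-trip is lossless for observed cells).
#'
#' @param fm a `feature_matrix`.
#' @return data.frame.
#' @export
decode_features <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  out <- as.data.frame(fm$x)
  for (cl in fm$categorical) {
    lev <- fm$codebook[[cl]]
    code <- pmin(pmax(round(out[[cl]]), 1), length(lev))
    out[[cl]] <- ifelse(is.na(out[[cl]]), NA_character_, lev[code])
  }
  out
}

#' Restrict a feature matrix to selected columns
#'
#' Keeps the target, strata and codebook intact, so a matrix imputed on the
#' full feature set can be restricted afterwards (e.g. to cultivar + tissue
#' for balance classification).
#'
#' @param fm a `feature_matrix`.
#' @param columns feature names to keep (must exist).
#' @return the restricted `feature_matrix`.
#' @export
select_features <- function(fm, columns) {
  stopifnot(inherits(fm, "feature_matrix"))
  missing_cols <- setdiff(columns, colnames(fm$x))
  if (length(missing_cols) > 0L)
    stop("unknown feature column(s): ", paste(missing_cols, collapse = ", "))
  fm$x <- fm$x[, columns, drop = FALSE]
  fm$missing_mask <- fm$missing_mask[, columns, drop = FALSE]
  fm$categorical <- intersect(fm$categorical, columns)
  fm$codebook <- fm$codebook[intersect(names(fm$codebook), columns)]
  fm
}

#' Replace tissue concentration features by their clr values
#'
#' Converts the `tissue_*` columns of a complete (imputed) feature matrix to
#' centered log-ratio values (closed at kappa = 1000 with the filling value),
#' mirroring the classification runs that use clr values rather than raw
#' concentrations as features. Apply after imputation: the clr of a row is
#' defined only when all 11 tissue parts are present.
#'
#' @param fm a complete `feature_matrix` containing all tissue columns.
#' @return a `feature_matrix` with `clr_*` columns in place of `tissue_*`.
#' @export
with_clr_tissue <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  tcols <- paste0("tissue_", tolower(onion_parts()))
  if (!all(tcols %in% colnames(fm$x)))
    stop("feature matrix lacks tissue column(s): ",
         paste(setdiff(tcols, colnames(fm$x)), collapse = ", "))
  if (any(is.na(fm$x[, tcols]))) stop("tissue columns have missing cells; impute first")
  clrm <- t(apply(fm$x[, tcols, drop = FALSE], 1, function(v) {
    unclass(clr_transform(close_composition(setNames(v, onion_parts()))))
  }))
  colnames(clrm) <- paste0("clr_", tolower(onion_parts(with_fv = TRUE)))
  keep <- setdiff(colnames(fm$x), tcols)
  mask_keep <- fm$missing_mask[, keep, drop = FALSE]
  tis_mask <- matrix(rowSums(fm$missing_mask[, tcols, drop = FALSE]) > 0,
                     nrow(clrm), ncol(clrm))
  colnames(tis_mask) <- colnames(clrm)
  fm$x <- cbind(fm$x[, keep, drop = FALSE], clrm)
  fm$missing_mask <- cbind(mask_keep, tis_mask)
  fm
}

#' Iterative random-forest imputation of missing feature values
#'
#' Fills missing cells by iterated model-based imputation: columns are
#' initialised with their mean (numeric) or modal code (categorical), then in
#' order of increasing missingness each incomplete column is regressed on all
#' other columns with a random forest and its missing cells replaced by the
#' forest predictions. Iteration stops when the mean absolute change at
#' imputed cells drops below `tol` of the column SD for every column, or after
#' `max_iter` rounds. Observed cells are never altered, and the procedure is
#' deterministic under `seed`.
#'
#' @param fm a `feature_matrix` (missing fraction must be below 50%).
#' @param seed integer seed.
#' @param max_iter maximum sweeps (default 10).
#' @param tol convergence tolerance as a fraction of column SD (default 1e-3).
#' @param num_trees trees per forest (default 50).
#' @return the `feature_matrix` with complete `x`; `missing_mask` still
#'   records which cells were imputed.
#' @export
impute_features <- function(fm, seed = 1L, max_iter = 10L, tol = 1e-3,
                            num_trees = 50L) {
  stopifnot(inherits(fm, "feature_matrix"))
  x <- fm$x
  mask <- fm$missing_mask
  if (!any(mask)) return(fm)
  if (mean(mask) >= 0.5)
    stop("missing fraction ", round(100 * mean(mask)), "% >= 50%; cannot impute")
  all_na <- colSums(!mask) == 0
  if (any(all_na))
    stop("cannot impute: column(s) entirely missing: ",
         paste(colnames(x)[all_na], collapse = ", "))

  for (j in seq_len(ncol(x))) {
    mj <- mask[, j]
    if (!any(mj)) next
    obs <- x[!mj, j]
    x[mj, j] <- if (colnames(x)[j] %in% fm$categorical)
      as.numeric(names(sort(table(obs), decreasing = TRUE))[1]) else mean(obs)
  }

  ord <- order(colSums(mask))
  ord <- ord[colSums(mask)[ord] > 0]
  sds <- apply(x, 2, sd)
  sds[sds == 0] <- 1
  for (it in seq_len(max_iter)) {
    prev <- x
    for (j in ord) {
      mj <- mask[, j]
      df <- as.data.frame(x[, -j, drop = FALSE])
      is_cat <- colnames(x)[j] %in% fm$categorical
      yj <- if (is_cat) factor(x[!mj, j]) else x[!mj, j]
      fit <- ranger::ranger(y = yj, x = df[!mj, , drop = FALSE],
                            num.trees = num_trees, num.threads = 1,
                            seed = derive_seed(seed, paste0("impute", it, ".", j)))
      pred <- predict(fit, df[mj, , drop = FALSE])$predictions
      x[mj, j] <- if (is_cat) as.numeric(as.character(pred)) else pred
    }
    delta <- vapply(ord, function(j)
      mean(abs(x[mask[, j], j] - prev[mask[, j], j])) / sds[j], numeric(1))
    if (all(delta < tol)) break
  }
  fm$x <- x
  fm
}

#' Stratified train/test partition
#'
#' Samples rows without replacement within each stratum at `train_fraction`
#' (rounded half-up per stratum), then adjusts single strata by ±1 row to hit
#' the global train count within one row. Singleton strata are assigned to the
#' training set with a warning. Train and test are disjoint and exhaustive.
#'
#' @param strata a `feature_matrix` or a vector of stratum labels.
#' @param train_fraction fraction of rows for training, in (0, 1).
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(strata, train_fraction = 0.7, seed = 1L) {
  if (inherits(strata, "feature_matrix")) strata <- strata$strata
  stopifnot(is.numeric(train_fraction), train_fraction > 0, train_fraction < 1)
  strata <- as.character(strata)
  n <- length(strata)
  levs <- sort(unique(strata))
  idx <- split(seq_len(n), factor(strata, levels = levs))
  sizes <- lengths(idx)
  if (any(sizes == 1L))
    warning("singleton stratum(s) assigned to train: ",
            paste(levs[sizes == 1L], collapse = ", "))
  half_up <- function(v) floor(v + 0.5)
  take <- half_up(sizes * train_fraction)
  take <- pmin(pmax(take, ifelse(sizes == 1L, 1L, 1L)),
               ifelse(sizes == 1L, 1L, sizes - 1L))
  target <- half_up(n * train_fraction)
  frac <- sizes * train_fraction - floor(sizes * train_fraction)
  while (sum(take) > target && any(adjustable <- take > 1 & sizes > 1)) {
    j <- which(adjustable)[which.min(frac[adjustable])]
    take[j] <- take[j] - 1L
    frac[j] <- frac[j] + 1     # don't pick the same stratum again first
  }
  while (sum(take) < target && any(adjustable <- take < sizes - 1 & sizes > 1)) {
    j <- which(adjustable)[which.max(frac[adjustable])]
    take[j] <- take[j] + 1L
    frac[j] <- frac[j] - 1
  }
  set.seed(seed)
  train <- unlist(lapply(seq_along(idx), function(j) {
    rows <- idx[[j]]
    if (length(rows) == 1L) rows else sort(sample(rows, take[j]))
  }), use.names = FALSE)
  train <- sort(train)
  list(train = train, test = setdiff(seq_len(n), train))
}

#' Write / read the delimited observation table
#'
#' Observations are stored as comma-separated text with a header row; missing
#' cells are empty.
#'
#' @param observations data.frame of trial observations.
#' @param path file path.
#' @return `write_observations()` returns `path` invisibly;
#'   `read_observations()` returns a data.frame.
#' @export
write_observations <- function(observations, path) {
  write.csv(observations, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  df
}
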