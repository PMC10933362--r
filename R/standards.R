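#' Derive cultivar-specific tissue nutrient standards from TN specimens
#'
#' For each cultivar with at least `min_n` true-negative specimens: tissue
#' compositions are closed at `kappa`, clr-transformed, summarised by
#' [fit_standard()] (per-part clr mean, SD and Student-t confidence interval
#' at level `1 - alpha`), and the clr mean is back-transformed to a centroid
#' in concentration units. Cultivars with fewer specimens are skipped with a
#' warning.
#'
#' @param tn_specimens data.frame with a `cultivar` column and tissue columns
#'   `tissue_n` ... `tissue_fe` (g/kg), typically from
#'   [select_true_negatives()]. Rows with missing tissue values are dropped.
#' @param alpha interval probability (default 0.01).
#' @param kappa measurement unit (default 1000 g/kg).
#' @param min_n minimum specimens per cultivar (default 2).
#' @param provenance optional list recorded with the table (cutoff, classifier
#'   config, feature space used).
#' @return object of class `standards_table`: `standards` (named list of
#'   `nutrient_standard`), `provenance` (includes TN counts per cultivar).
#' @export
derive_standards <- function(tn_specimens, alpha = 0.01, kappa = 1000,
                             min_n = 2L, provenance = list()) {
  stopifnot(is.data.frame(tn_specimens), "cultivar" %in% names(tn_specimens))
  tcols <- paste0("tissue_", tolower(onion_parts()))
  if (!all(tcols %in% names(tn_specimens)))
    stop("missing tissue column(s): ",
         paste(setdiff(tcols, names(tn_specimens)), collapse = ", "))
  tm <- as.matrix(tn_specimens[tcols])
  keep <- rowSums(is.na(tm)) == 0
  tn_specimens <- tn_specimens[keep, , drop = FALSE]
  tm <- tm[keep, , drop = FALSE]
  counts <- table(tn_specimens$cultivar)
  skipped <- names(counts)[counts < min_n]
  if (length(skipped) > 0L)
    warning("skipping cultivar(s) with fewer than ", min_n,
            " TN specimens: ", paste(skipped, collapse = ", "))
  keep_cv <- names(counts)[counts >= min_n]
  if (length(keep_cv) == 0L)
    stop("empty standards: no cultivar has enough TN specimens")
  stds <- lapply(keep_cv, function(cv) {
    rows <- which(tn_specimens$cultivar == cv)
    clrs <- lapply(rows, function(i)
      clr_transform(close_composition(setNames(tm[i, ], onion_parts()),
                                      kappa = kappa)))
    fit_standard(clrs, cultivar = cv, alpha = alpha, kappa = kappa)
  })
  names(stds) <- keep_cv
  provenance$tn_counts <- as.list(counts[keep_cv])
  provenance$alpha <- alpha
  provenance$kappa <- kappa
  structure(list(standards = stds, provenance = provenance),
            class = "standards_table")
}

#' @export
print.standards_table <- function(x, ...) {
  cat("Standards for", length(x$standards), "cultivar(s):",
      paste(names(x$standards), collapse = ", "), "\n")
  for (s in x$standards) print(s)
  invisible(x)
}

#' Concentration quartiles of reference specimens by cultivar
#'
#' Lower (25th) and higher (75th) percentiles of raw tissue nutrient
#' concentrations per cultivar × nutrient, using linear interpolation between
#' order statistics (R's default type-7 rule), for cultivars with at least
#' `min_n` specimens.
#'
#' @param tn_specimens as in [derive_standards()].
#' @param min_n minimum specimens per cultivar (default 4).
#' @return data.frame with columns `cultivar`, `nutrient`, `lq`, `hq` (g/kg).
#' @export
concentration_quartiles <- function(tn_specimens, min_n = 4L) {
  stopifnot(is.data.frame(tn_specimens), "cultivar" %in% names(tn_specimens))
  tcols <- paste0("tissue_", tolower(onion_parts()))
  tm <- as.matrix(tn_specimens[intersect(tcols, names(tn_specimens))])
  keep <- rowSums(is.na(tm)) == 0
  tn_specimens <- tn_specimens[keep, , drop = FALSE]
  tm <- tm[keep, , drop = FALSE]
  counts <- table(tn_specimens$cultivar)
  skipped <- names(counts)[counts < min_n]
  if (length(skipped) > 0L)
    warning("skipping cultivar(s) with fewer than ", min_n,
            " specimens: ", paste(skipped, collapse = ", "))
  keep_cv <- names(counts)[counts >= min_n]
  out <- do.call(rbind, lapply(keep_cv, function(cv) {
    sub <- tm[tn_specimens$cultivar == cv, , drop = FALSE]
    do.call(rbind, lapply(seq_len(ncol(sub)), function(j) {
      q <- quantile(sub[, j], c(0.25, 0.75), type = 7, names = FALSE)
      data.frame(cultivar = cv,
                 nutrient = onion_parts()[j],
                 lq = q[1], hq = q[2])
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Diagnose a specimen against cultivar nutrient standards
#'
#' Computes nutrient balance indices of the specimen against its cultivar's
#' standard, assigns a verdict per part (excess when the index exceeds
#' `index_threshold`, shortage below `-index_threshold`, balanced otherwise),
#' and optionally lists the nearest nutritionally balanced reference
#' compositions by clr Euclidean distance.
#'
#' @param specimen a `composition` (or `clr_vector`).
#' @param standards a `standards_table`.
#' @param cultivar cultivar whose standard to diagnose against.
#' @param reference_bank optional list/matrix of reference clr vectors for
#'   neighbour search.
#' @param k neighbours to report (default 5).
#' @param index_threshold verdict threshold in standard deviations
#'   (default 1).
#' @return object of class `diagnosis`: `cultivar`, `indices`, `verdict`,
#'   `neighbors` (or NULL), `threshold`.
#' @export
diagnose <- function(specimen, standards, cultivar, reference_bank = NULL,
                     k = 5L, index_threshold = 1) {
  stopifnot(inherits(standards, "standards_table"))
  std <- standards$standards[[cultivar]]
  if (is.null(std))
    stop("no standard for cultivar '", cultivar, "'; available: ",
         paste(names(standards$standards), collapse = ", "))
  cv <- if (is_composition(specimen)) clr_transform(specimen) else specimen
  idx <- nutrient_indices(cv, std)
  verdict <- ifelse(idx > index_threshold, "excess",
             ifelse(idx < -index_threshold, "shortage", "balanced"))
  nb <- if (!is.null(reference_bank))
    nearest_balanced_neighbors(cv, reference_bank, k) else NULL
  structure(list(cultivar = cultivar, indices = idx, verdict = verdict,
                 neighbors = nb, threshold = index_threshold),
            class = "diagnosis")
}

#' @export
print.diagnosis <- function(x, ...) {
  cat("Diagnosis against standard for", x$cultivar,
      sprintf("(threshold %.1f SD)\n", x$threshold))
  print(data.frame(part = names(x$indices), index = round(x$indices, 2),
                   verdict = x$verdict, row.names = NULL))
  if (!is.null(x$neighbors)) {
    cat("Nearest balanced neighbours:\n")
    print(x$neighbors)
  }
  invisible(x)
}

#' Histogram of nutrient balance indices
#'
#' @param x a `diagnosis`.
#' @param ... passed to [graphics::barplot()].
#' @return the diagnosis, invisibly.
#' @export
plot.diagnosis <- function(x, ...) {
  graphics::barplot(x$indices, las = 2, ylab = "balance index (SD units)", ...)
  graphics::abline(h = c(-x$threshold, 0, x$threshold), lty = c(2, 1, 2))
  invisible(x)
}
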