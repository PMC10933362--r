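#' RReliefF feature relevance for a regression target
#'
#' Regression Relief estimator: features are scored by how strongly their
#' differences track target differences among nearest neighbours, which
#' captures feature interactions that univariate screens miss. For each
#' sampled instance the k nearest neighbours (range-normalised Manhattan
#' distance; categorical features contribute 0/1) receive exponentially
#' decaying rank weights \eqn{w_r \propto \exp(-(r/\sigma)^2)} normalised to
#' sum 1, and three accumulators are updated: the probability mass of a
#' different target value \eqn{N_{dC}}, of a different feature value
#' \eqn{N_{dF}[f]}, and of both \eqn{N_{dC \wedge dF}[f]}. The relevance of
#' feature f after m sampled instances is
#' \deqn{W[f] = N_{dC \wedge dF}/N_{dC} - (N_{dF} - N_{dC \wedge dF})/(m - N_{dC}).}
#' Scores near zero indicate irrelevance; large positive scores indicate
#' features whose variation aligns with target variation in local
#' neighbourhoods.
#'
#' @param x numeric feature matrix or a `feature_matrix` (must be complete).
#' @param target numeric target vector (defaults to the `feature_matrix`
#'   target); must not be constant.
#' @param k number of nearest neighbours (default 10).
#' @param iterations number of sampled instances; default all rows, in a
#'   seed-driven random order.
#' @param seed integer seed driving the sample order.
#' @param categorical names of categorical columns (taken from the
#'   `feature_matrix` when given).
#' @param sigma rank-weight scale (default 20).
#' @param sample_order optional explicit instance order (overrides
#'   `seed`/`iterations`); used e.g. to show row-permutation invariance.
#' @return object of class `relevance_report`: `method`, `scores` (named),
#'   `ranking` (feature names by descending score), `params`.
#' @export
rrelieff <- function(x, target = NULL, k = 10L, iterations = NULL, seed = 1L,
                     categorical = NULL, sigma = 20, sample_order = NULL) {
  if (inherits(x, "feature_matrix")) {
    if (is.null(target)) target <- x$target
    if (is.null(categorical)) categorical <- x$categorical
    x <- x$x
  }
  stopifnot(is.matrix(x), is.numeric(target), length(target) == nrow(x))
  if (any(is.na(x)) || any(is.na(target)))
    stop("RReliefF requires a complete matrix and target (impute first)")
  n <- nrow(x)
  if (k >= n) stop("parameter error: k must be smaller than the number of rows")
  yrange <- diff(range(target))
  if (yrange == 0) stop("undefined relevance: constant target")

  is_cat <- colnames(x) %in% categorical
  ranges <- apply(x, 2, function(col) diff(range(col)))
  ranges[ranges == 0] <- Inf          # constant feature -> diff 0 everywhere

  ord <- if (!is.null(sample_order)) sample_order else {
    set.seed(seed)
    m <- if (is.null(iterations)) n else min(iterations, n)
    sample(n, m)
  }
  m <- length(ord)
  w <- exp(-(seq_len(k) / sigma)^2)
  w <- w / sum(w)

  ndc <- 0
  ndf <- numeric(ncol(x))
  ndcdf <- numeric(ncol(x))
  for (i in ord) {
    dmat <- abs(x - matrix(x[i, ], n, ncol(x), byrow = TRUE))
    dmat <- sweep(dmat, 2, ranges, "/")
    if (any(is_cat))
      dmat[, is_cat] <- (dmat[, is_cat, drop = FALSE] > 0) + 0
    dist <- rowSums(dmat)
    dist[i] <- Inf
    nb <- order(dist)[seq_len(k)]
    dy <- abs(target[nb] - target[i]) / yrange
    ndc <- ndc + sum(w * dy)
    ndf <- ndf + colSums(w * dmat[nb, , drop = FALSE])
    ndcdf <- ndcdf + colSums((w * dy) * dmat[nb, , drop = FALSE])
  }
  scores <- ndcdf / ndc - (ndf - ndcdf) / (m - ndc)
  names(scores) <- colnames(x)
  new_relevance_report("rrelieff", scores,
                       list(k = k, iterations = m, seed = seed, sigma = sigma))
}

#' Gain ratio of features against a class label
#'
#' Information gain of each feature about the class, normalised by the
#' feature's split information (both in bits), so scores lie in `[0, 1]`.
#' Continuous features are discretised into equal-frequency bins (default 4;
#' ties broken by row order); features with at most `bins` distinct values are
#' used as discrete directly. A feature whose split information is zero (a
#' constant) scores 0.
#'
#' @param x numeric feature matrix or `feature_matrix` (complete).
#' @param class_labels factor/character/logical class per row (at least two
#'   classes present), e.g. high/low yield at a cutoff.
#' @param bins number of equal-frequency bins (default 4).
#' @param categorical names of categorical columns.
#' @return a `relevance_report` with `method = "gain_ratio"`.
#' @export
gain_ratio <- function(x, class_labels, bins = 4L, categorical = NULL) {
  if (inherits(x, "feature_matrix")) {
    if (is.null(categorical)) categorical <- x$categorical
    x <- x$x
  }
  stopifnot(is.matrix(x), length(class_labels) == nrow(x))
  if (any(is.na(x)) || any(is.na(class_labels)))
    stop("gain ratio requires complete data")
  cls <- as.factor(class_labels)
  if (nlevels(droplevels(cls)) < 2L)
    stop("undefined entropy: a single class is present")
  cls <- droplevels(cls)
  h <- function(counts) {
    p <- counts / sum(counts)
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  hy <- h(table(cls))
  scores <- vapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    d <- if (colnames(x)[j] %in% categorical || length(unique(v)) <= bins)
      factor(v)
    else
      cut(rank(v, ties.method = "first"), breaks = bins)
    tab <- table(d, cls)
    nj <- rowSums(tab)
    cond <- sum((nj / sum(nj)) * apply(tab, 1, h))
    si <- h(nj)
    if (si == 0) 0 else (hy - cond) / si
  }, numeric(1))
  names(scores) <- colnames(x)
  new_relevance_report("gain_ratio", scores, list(bins = bins))
}

new_relevance_report <- function(method, scores, params) {
  structure(list(method = method, scores = scores,
                 ranking = names(sort(scores, decreasing = TRUE)),
                 params = params),
            class = "relevance_report")
}

#' @export
print.relevance_report <- function(x, n = 10, ...) {
  cat("Feature relevance (", x$method, ")\n", sep = "")
  top <- sort(x$scores, decreasing = TRUE)
  print(round(head(top, n), 4))
  invisible(x)
}

#' Write a relevance report as delimited text
#'
#' @param report a `relevance_report`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_relevance <- function(report, path) {
  ord <- order(report$scores, decreasing = TRUE)
  write.csv(data.frame(feature = names(report$scores)[ord],
                       score = as.numeric(report$scores)[ord],
                       rank = seq_along(ord),
                       method = report$method),
            path, row.names = FALSE)
  invisible(path)
}

#' Bar chart of feature relevance scores
#'
#' @param x a `relevance_report`.
#' @param n number of top features to display.
#' @param ... passed to [graphics::barplot()].
#' @return the report, invisibly.
#' @export
plot.relevance_report <- function(x, n = 15, ...) {
  top <- rev(head(sort(x$scores, decreasing = TRUE), n))
  graphics::barplot(top, horiz = TRUE, las = 1,
                    xlab = paste(x$method, "score"), ...)
  invisible(x)
}
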