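#' Close a tissue nutrient composition to the measurement unit
#'
#' Tissue nutrient concentrations are parts of a composition constrained to the
#' measurement unit (1000 g/kg for tissue tests). The composition is closed by
#' a filling value \eqn{F_v = \kappa - \sum_i c_i}, appended as the last part,
#' so that the full vector of D parts sums exactly to \eqn{\kappa}.
#'
#' @param concentrations named numeric vector of nutrient concentrations in
#'   g/kg. Names must be a subset of [onion_parts()]; parts are reordered to
#'   the canonical order. Unnamed vectors of length 11 are assumed to be in
#'   canonical order already.
#' @param kappa measurement-unit total in g/kg (default 1000).
#' @param labels canonical part order (default [onion_parts()]).
#' @return an object of class `composition`: list with `labels`,
#'   `concentrations` (named, canonical order), `kappa` and `fv`.
#' @export
#' @examples
#' comp <- close_composition(c(N = 30, P = 4, K = 25, Ca = 10, Mg = 3, S = 7,
#'                             B = 0.04, Cu = 0.03, Zn = 0.06, Mn = 0.13, Fe = 0.07))
#' comp$fv
close_composition <- function(concentrations, kappa = 1000, labels = onion_parts()) {
  stopifnot(is.numeric(concentrations), is.numeric(kappa), length(kappa) == 1L,
            kappa > 0)
  if (is.null(names(concentrations))) {
    if (length(concentrations) != length(labels))
      stop("unnamed concentrations must have length ", length(labels))
    names(concentrations) <- labels
  }
  if (!all(names(concentrations) %in% labels))
    stop("unknown part(s): ",
         paste(setdiff(names(concentrations), labels), collapse = ", "))
  if (!all(labels %in% names(concentrations)))
    stop("missing part(s): ",
         paste(setdiff(labels, names(concentrations)), collapse = ", "))
  x <- concentrations[labels]
  bad <- !is.finite(x) | x <= 0
  if (any(bad))
    stop("invalid composition: non-positive or non-finite concentration for part(s) ",
         paste(labels[bad], collapse = ", "))
  if (sum(x) >= kappa)
    stop("closure violation: concentrations sum to ", format(sum(x)),
         " g/kg >= kappa = ", kappa)
  structure(list(labels = labels, concentrations = x, kappa = kappa,
                 fv = kappa - sum(x)),
            class = "composition")
}

#' @export
print.composition <- function(x, ...) {
  cat("Tissue composition (g/kg, kappa =", x$kappa, ")\n")
  print(round(c(x$concentrations, Fv = x$fv), 4))
  invisible(x)
}

#' Full part vector of a composition (nutrients + filling value)
#'
#' @param comp a `composition`.
#' @return named numeric vector of all D parts, `Fv` last; sums to `kappa`.
#' @export
composition_parts <- function(comp) c(comp$concentrations, Fv = comp$fv)

is_composition <- function(x) inherits(x, "composition")

#' Construct a clr vector
#'
#' Mostly internal; users normally obtain clr vectors from [clr_transform()].
#'
#' @param values numeric vector of log-ratios, one per part including `Fv`.
#' @param labels part names; default canonical order with `Fv` last.
#' @return classed named numeric vector (`clr_vector`).
#' @export
clr_vector <- function(values, labels = onion_parts(with_fv = TRUE)) {
  stopifnot(is.numeric(values))
  if (is.null(names(values))) {
    stopifnot(length(values) == length(labels))
    names(values) <- labels
  }
  if (!all(is.finite(values))) stop("non-finite clr value")
  structure(as.numeric(setNames(values[labels], labels)),
            names = labels, class = "clr_vector")
}

#' Centered log-ratio transform of a closed composition
#'
#' Each part, including the filling value, is centered on the geometric mean
#' across all D parts: \eqn{clr_i = \ln(x_i / G)} with
#' \eqn{G = (\prod_j x_j)^{1/D}}. The resulting vector sums to zero and lives
#' in unconstrained real space, where ordinary means, variances and Euclidean
#' distances are unbiased by the closure.
#'
#' @param comp a `composition` from [close_composition()].
#' @return a `clr_vector` (named numeric, parts + `Fv`, sum zero).
#' @export
#' @examples
#' comp <- close_composition(setNames(rep(83, 11), onion_parts()), kappa = 996)
#' clr_transform(comp)  # all parts equal -> all zeros
clr_transform <- function(comp) {
  if (!is_composition(comp)) stop("`comp` must be a composition")
  x <- c(comp$concentrations, Fv = comp$fv)
  lx <- log(x)
  clr_vector(lx - mean(lx), labels = names(x))
}

#' Back-transform clr values to concentrations
#'
#' Inverse of [clr_transform()]: \eqn{x_i = \kappa \exp(clr_i) / \sum_j \exp(clr_j)}.
#' The closure normalisation absorbs any constant offset, so the input is not
#' required to sum to zero (a warning is issued when the sum departs from zero
#' by more than 1e-6, as for midpoints of rounded interval endpoints).
#'
#' @param clr a `clr_vector` or named numeric vector over all D parts
#'   (`Fv` last).
#' @param kappa measurement-unit total (default 1000 g/kg).
#' @return a `composition`; the last input part becomes the filling value.
#' @export
clr_back_transform <- function(clr, kappa = 1000) {
  v <- unclass(clr)
  if (!is.numeric(v) || !all(is.finite(v)))
    stop("numeric-input error: clr values must be finite numerics")
  if (abs(sum(v)) > 1e-6)
    warning("clr input sums to ", format(sum(v)),
            "; closure absorbs the offset")
  e <- exp(v - max(v))        # guard against overflow; closure removes shift
  x <- kappa * e / sum(e)
  labs <- names(v)
  if (is.null(labs)) labs <- onion_parts(with_fv = TRUE)
  close_composition(setNames(x[-length(x)], labs[-length(labs)]), kappa = kappa,
                    labels = labs[-length(labs)])
}

#' Euclidean distance between clr vectors
#'
#' Compositional proximity between a diagnosed specimen and a reference:
#' \eqn{\epsilon = \sqrt{\sum_k (clr_k - clr_k^*)^2}}. clr space has Euclidean
#' geometry, so this is a proper metric on compositions.
#'
#' @param a,b `clr_vector`s (or named numerics) with identical labels.
#' @return nonnegative numeric scalar.
#' @export
clr_distance <- function(a, b) {
  a <- unclass(a); b <- unclass(b)
  if (length(a) != length(b) ||
      (!is.null(names(a)) && !is.null(names(b)) && !identical(names(a), names(b))))
    stop("incompatible vectors: labels or lengths differ")
  sqrt(sum((a - b)^2))
}

#' Fit a cultivar tissue nutrient standard from reference specimens
#'
#' Computes per-part sample means and standard deviations of the clr values of
#' nutritionally balanced, high-yielding specimens, with two-sided Student-t
#' confidence intervals at level `1 - alpha` on each part mean
#' (mean ± t(1 - alpha/2, n-1) · SD/√n), and back-transforms the clr mean to a
#' centroid composition in familiar concentration units.
#'
#' @param specimens list of `clr_vector`s, or a numeric matrix with one
#'   specimen per row and parts as columns.
#' @param cultivar cultivar label stored with the standard.
#' @param alpha two-sided interval probability (default 0.01, i.e. 99% C.I.).
#' @param kappa measurement unit for the centroid back-transform.
#' @return an object of class `nutrient_standard`: `cultivar`, `labels`,
#'   `clr_mean`, `clr_sd`, `ci_low`, `ci_high`, `alpha`, `n`, `centroid`
#'   (a `composition`) and `degenerate` (TRUE when some part has zero
#'   variance, in which case the interval collapses to the mean).
#' @export
fit_standard <- function(specimens, cultivar, alpha = 0.01, kappa = 1000) {
  if (!(is.numeric(alpha) && length(alpha) == 1L && alpha > 0 && alpha < 1))
    stop("parameter error: alpha must lie in (0, 1)")
  m <- if (is.matrix(specimens)) specimens else {
    if (length(specimens) < 1L) stop("insufficient data: no specimens")
    labs <- names(unclass(specimens[[1]]))
    do.call(rbind, lapply(specimens, function(s) {
      v <- unclass(s)
      if (!identical(names(v), labs)) stop("incompatible vectors: labels differ")
      v
    }))
  }
  n <- nrow(m)
  if (n < 2L) stop("insufficient data: need at least 2 specimens, got ", n)
  mu <- colMeans(m)
  sdv <- apply(m, 2, sd)
  degenerate <- any(sdv == 0)
  if (degenerate)
    warning("insufficient variance: zero clr SD on part(s) ",
            paste(colnames(m)[sdv == 0], collapse = ", "))
  tcrit <- qt(1 - alpha / 2, df = n - 1)
  half <- tcrit * sdv / sqrt(n)
  structure(list(cultivar = cultivar, labels = colnames(m),
                 clr_mean = mu, clr_sd = sdv,
                 ci_low = mu - half, ci_high = mu + half,
                 alpha = alpha, n = n,
                 centroid = clr_back_transform(setNames(mu, colnames(m)), kappa),
                 degenerate = degenerate),
            class = "nutrient_standard")
}

#' @export
print.nutrient_standard <- function(x, ...) {
  cat("Nutrient standard for cultivar", x$cultivar,
      sprintf("(n = %d, %.0f%% C.I.)\n", x$n, 100 * (1 - x$alpha)))
  print(data.frame(part = x$labels,
                   clr_mean = round(x$clr_mean, 3),
                   clr_sd = round(x$clr_sd, 3),
                   ci_low = round(x$ci_low, 3),
                   ci_high = round(x$ci_high, 3),
                   centroid = signif(composition_parts(x$centroid), 4),
                   row.names = NULL))
  invisible(x)
}

#' Nutrient balance indices of a specimen against a standard
#'
#' The index of part i is \eqn{I_i = (clr_i - clr_i^*) / SD_i^*}: the
#' specimen's clr value standardised by the reference mean and standard
#' deviation. Positive values indicate relative excess, negative values
#' relative shortage of the nutrient.
#'
#' @param specimen a `clr_vector`.
#' @param std a `nutrient_standard`.
#' @return named numeric vector of indices (one per part, including `Fv`).
#' @export
nutrient_indices <- function(specimen, std) {
  stopifnot(inherits(std, "nutrient_standard"))
  v <- unclass(specimen)
  if (!identical(names(v), std$labels))
    stop("incompatible vectors: specimen labels differ from standard")
  zero <- std$clr_sd == 0
  if (any(zero))
    stop("degenerate standard: zero SD on part(s) ",
         paste(std$labels[zero], collapse = ", "))
  (v - std$clr_mean) / std$clr_sd
}

#' Nearest nutritionally balanced neighbours in clr space
#'
#' Returns the `k` members of a reference bank with the shortest Euclidean
#' distance \eqn{\epsilon} to the diagnosed specimen, in ascending order.
#' Ties are broken by bank order, so output is deterministic.
#'
#' @param specimen a `clr_vector`.
#' @param bank list of `clr_vector`s or matrix (one reference per row).
#' @param k number of neighbours (>= 1); capped at the bank size.
#' @return data.frame with columns `index` (position in the bank) and
#'   `epsilon`.
#' @export
nearest_balanced_neighbors <- function(specimen, bank, k = 5) {
  stopifnot(k >= 1)
  m <- if (is.matrix(bank)) bank else {
    if (length(bank) < 1L) stop("no-reference error: bank is empty")
    do.call(rbind, lapply(bank, unclass))
  }
  if (nrow(m) < 1L) stop("no-reference error: bank is empty")
  v <- unclass(specimen)
  if (ncol(m) != length(v)) stop("incompatible vectors: lengths differ")
  d <- sqrt(rowSums((m - matrix(v, nrow(m), length(v), byrow = TRUE))^2))
  ord <- order(d)          # stable: ties keep bank order
  ord <- ord[seq_len(min(k, length(ord)))]
  data.frame(index = ord, epsilon = d[ord])
}
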