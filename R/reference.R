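#' Published clr confidence intervals for balanced onion cultivars
#'
#' Reference tissue nutrient standards for four onion cultivars grown in
#' Santa Catarina (Brazil): 99% confidence intervals about clr means of
#' nutritionally balanced specimens yielding above 50 Mg/ha, together with the
#' published back-transformed centroid concentrations (g/kg). These values
#' seed the synthetic generator's cultivar ionome centers and serve as a
#' desk-scale consistency check of the clr algebra: back-transforming the
#' interval midpoints reproduces the centroid column within print rounding.
#'
#' The published table contains one typographical slip: the lower K bound for
#' 'SCS373 Valessul' appears as "3/234" and is read here as 3.234 (see
#' [read_clr_ci()], which warns when parsing that form).
#'
#' @return data.frame with columns `cultivar`, `part`, `ci_low`, `ci_high`,
#'   `centroid` (12 parts per cultivar, canonical order, `Fv` last).
#' @export
#' @examples
#' ref <- onion_clr_reference()
#' mid <- clr_reference_midpoints("Caeté")
#' composition_parts(clr_back_transform(mid))[["N"]]  # ~30.7 g/kg
onion_clr_reference <- function() {
  parts <- onion_parts(with_fv = TRUE)
  mk <- function(cultivar, lo, hi, cen)
    data.frame(cultivar = cultivar, part = parts, ci_low = lo, ci_high = hi,
               centroid = cen)
  rbind(
    mk("Caeté",
       c(2.859, 0.854, 2.685, 1.748, 0.644, 1.449, -3.859, -3.951, -3.332, -2.794, -3.364, 6.259),
       c(2.935, 1.008, 2.749, 1.813, 0.712, 1.575, -3.726, -3.850, -3.241, -2.366, -3.138, 6.329),
       c(30.7, 4.3, 25.7, 10.1, 3.3, 7.7, 0.038, 0.034, 0.063, 0.129, 0.066, 917.9)),
    mk("Mulata",
       c(3.334, 0.995, 3.370, 2.560, 0.724, 0.823, -3.815, -4.862, -3.681, -2.825, -4.362, 6.522),
       c(3.418, 1.106, 3.504, 2.725, 0.898, 1.023, -3.611, -4.406, -3.395, -2.655, -3.983, 6.592),
       c(37.2, 3.6, 39.5, 17.9, 2.9, 3.2, 0.031, 0.012, 0.037, 0.082, 0.020, 895.5)),
    mk("Omega",
       c(3.109, 1.073, 3.265, 2.624, 0.917, 0.912, -3.619, -5.067, -3.628, -2.913, -4.040, 6.701),
       c(3.177, 1.137, 3.341, 2.726, 1.017, 1.013, -3.536, -4.832, -3.464, -2.813, -3.842, 6.743),
       c(25.6, 3.3, 30.1, 16.1, 2.9, 2.9, 0.031, 0.008, 0.032, 0.063, 0.021, 918.9)),
    mk("SCS373 Valessul",
       c(3.172, 1.864, 3.234, 2.011, 0.864, 1.369, -4.063, -4.687, -3.873, -4.089, -3.147, 6.722),
       c(3.262, 1.913, 3.314, 2.117, 0.919, 1.475, -3.973, -4.398, -3.784, -3.954, -3.058, 6.789),
       c(26.8, 7.1, 28.4, 8.5, 2.6, 4.4, 0.019, 0.011, 0.023, 0.019, 0.048, 922.1))
  )
}

#' Cultivars with published reference standards
#' @return character vector of cultivar names.
#' @export
reference_cultivars <- function() unique(onion_clr_reference()$cultivar)

#' clr confidence-interval midpoints of a reference cultivar
#'
#' @param cultivar one of [reference_cultivars()].
#' @return a `clr_vector` of the 12 interval midpoints (canonical order).
#' @export
clr_reference_midpoints <- function(cultivar) {
  ref <- onion_clr_reference()
  rows <- ref[ref$cultivar == cultivar, ]
  if (nrow(rows) == 0L)
    stop("no reference for cultivar '", cultivar, "'; available: ",
         paste(reference_cultivars(), collapse = ", "))
  mid <- (rows$ci_low + rows$ci_high) / 2
  structure(setNames(mid, rows$part), class = "clr_vector")
}

#' Read a clr confidence-interval table from delimited text
#'
#' Reads a table shaped like [onion_clr_reference()] (columns `cultivar`,
#' `part`, `ci_low`, `ci_high`, `centroid`; comma-separated, header row).
#' Numeric cells accidentally typed with a slash as decimal separator
#' (e.g. "3/234") are repaired to the dot form with a warning rather than
#' silently dropped.
#'
#' @param path file path.
#' @return data.frame in the same shape as [onion_clr_reference()].
#' @export
read_clr_ci <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("cultivar", "part", "ci_low", "ci_high", "centroid")
  if (!all(need %in% names(df)))
    stop("clr C.I. file must have columns ", paste(need, collapse = ", "))
  fix <- function(col, nm) {
    slash <- grepl("^\\s*-?[0-9]+/[0-9]+\\s*$", col)
    if (any(slash)) {
      warning("column '", nm, "': value(s) ",
              paste(unique(col[slash]), collapse = ", "),
              " use '/' as decimal separator; reading as '.'")
      col[slash] <- sub("/", ".", col[slash], fixed = TRUE)
    }
    as.numeric(col)
  }
  for (nm in c("ci_low", "ci_high", "centroid")) df[[nm]] <- fix(df[[nm]], nm)
  df
}

#' Write / read a standards table as delimited text
#'
#' The on-disk layout mirrors the published standards tables: one row per
#' cultivar × part with the interval bounds, clr mean and SD, back-transformed
#' centroid concentration, specimen count and interval level.
#'
#' @param standards a `standards_table` (see [derive_standards()]) or a single
#'   `nutrient_standard`.
#' @param path output file path.
#' @return `write_standards()` returns `path` invisibly; `read_standards()`
#'   returns a data.frame.
#' @export
write_standards <- function(standards, path) {
  write.csv(standards_as_data_frame(standards), path, row.names = FALSE,
            quote = TRUE)
  invisible(path)
}

#' @rdname write_standards
#' @export
read_standards <- function(path) read.csv(path, stringsAsFactors = FALSE)

standards_as_data_frame <- function(standards) {
  stds <- if (inherits(standards, "nutrient_standard")) list(standards)
          else standards$standards
  do.call(rbind, lapply(stds, function(s)
    data.frame(cultivar = s$cultivar, part = s$labels,
               ci_low = s$ci_low, ci_high = s$ci_high,
               clr_mean = s$clr_mean, clr_sd = s$clr_sd,
               centroid = composition_parts(s$centroid),
               n = s$n, alpha = s$alpha, row.names = NULL)))
}
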