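#' Standardized Shannon diversity index of seasonal rainfall
#'
#' Quantifies how evenly rainfall was distributed over the growing season:
#' \eqn{SDI = -\sum_i p_i \ln(p_i) / \ln(n)}, where \eqn{p_i} is the fraction
#' of the season's cumulated precipitation falling on day i and n the season
#' length in days. Days with zero rain contribute zero (the convention
#' \eqn{0 \cdot \ln 0 = 0}). SDI = 1 means perfectly uniform rainfall; SDI = 0
#' means the whole season's rain fell on a single day.
#'
#' @param daily_rain nonnegative numeric vector of daily rainfall (mm), one
#'   value per day of the season.
#' @return numeric scalar in `[0, 1]`.
#' @export
#' @examples
#' sdi(rep(5, 120))          # 1: uniform
#' sdi(c(600, rep(0, 119)))  # 0: concentrated in one day
#' sdi(c(10, 10, 0, 0))      # log(2)/log(4) = 0.5
sdi <- function(daily_rain) {
  stopifnot(is.numeric(daily_rain))
  if (any(!is.finite(daily_rain)) || any(daily_rain < 0))
    stop("daily rainfall must be finite and nonnegative")
  n <- length(daily_rain)
  if (n < 2L)
    stop("undefined SDI: season length must be >= 2 days (ln(n) = 0 at n = 1)")
  total <- sum(daily_rain)
  if (total <= 0) stop("undefined SDI: all-zero rainfall series")
  p <- daily_rain / total
  terms <- ifelse(p > 0, p * log(p), 0)
  -sum(terms) / log(n) + 0   # + 0 normalises IEEE negative zero
}

#' Cumulated degree-days above a base temperature
#'
#' Simple-average method: each day contributes
#' \eqn{\max(0, (T_{max} + T_{min})/2 - T_{base})}; days with mean temperature
#' below base contribute zero, never negative. The default base of 5 °C is
#' the convention for cold-season crops such as onion.
#'
#' @param tmin,tmax aligned numeric vectors of daily minimum and maximum air
#'   temperature (°C).
#' @param base base temperature (°C, default 5).
#' @return cumulated degree-days (°C·day).
#' @export
#' @examples
#' degree_days(10, 20)  # one day, mean 15 -> 10 degree-days
degree_days <- function(tmin, tmax, base = 5) {
  if (length(tmin) != length(tmax))
    stop("input error: tmin and tmax must have the same length")
  if (any(tmin > tmax)) stop("input error: tmin exceeds tmax on some day(s)")
  sum(pmax(0, (tmin + tmax) / 2 - base))
}

#' Exchangeable soil acidity from SMP-buffer pH
#'
#' Estimates exchangeable acidity (cmol_c/dm3) from the pH of soil in SMP
#' buffer. Two variants are exposed. The `"corrected"` variant (default)
#' evaluates \eqn{10^{(7.76 - 1.053 \cdot pH_{SMP})}}, the standard
#' SMP-calibration shape in which acidity decreases with buffer pH. The
#' `"literal"` variant evaluates \eqn{10 e^{(7.76 + 1.053 \cdot pH_{SMP})}}
#' exactly as that expression is sometimes reproduced in print; it increases
#' with pH and produces physically implausible magnitudes, and is provided
#' only so both calibration forms can be compared explicitly.
#'
#' @param pH_SMP numeric vector of SMP-buffer pH values; a warning is issued
#'   outside the sanity range `[3, 8]` but values are still returned.
#' @param variant `"corrected"` (default) or `"literal"`.
#' @return exchangeable acidity, cmol_c/dm3 (vectorised).
#' @export
#' @examples
#' exchangeable_acidity(6.0)  # 10^(7.76 - 6.318) ~ 27.7
exchangeable_acidity <- function(pH_SMP, variant = c("corrected", "literal")) {
  if (missing(variant) && !isTRUE(.oniondx$acidity_note_shown)) {
    message("exchangeable_acidity(): using the 'corrected' SMP calibration ",
            "10^(7.76 - 1.053*pH_SMP); the 'literal' printed form ",
            "10*exp(7.76 + 1.053*pH_SMP) increases with pH and is exposed ",
            "via variant = 'literal'. (shown once per session)")
    .oniondx$acidity_note_shown <- TRUE
  }
  variant <- match.arg(variant)
  stopifnot(is.numeric(pH_SMP))
  out <- pH_SMP < 3 | pH_SMP > 8
  if (any(out, na.rm = TRUE))
    warning("pH_SMP outside the sanity range [3, 8]: ",
            paste(pH_SMP[out], collapse = ", "))
  switch(variant,
         corrected = 10^(7.76 - 1.053 * pH_SMP),
         literal   = 10 * exp(7.76 + 1.053 * pH_SMP))
}

#' Cation exchange capacity and base saturation
#'
#' CEC is the sum of exchangeable basic cations (Ca, Mg, K) and exchangeable
#' acidity; base saturation is the basic-cation share of CEC in percent.
#'
#' @param Ca,Mg,K exchangeable cations, cmol_c/dm3 (nonnegative; vectorised).
#' @param acidity exchangeable acidity, cmol_c/dm3.
#' @return list with numeric elements `cec` (cmol_c/dm3) and
#'   `base_saturation` (%).
#' @export
#' @examples
#' cec_and_base_saturation(1, 1, 1, 1)  # cec 4, saturation 75%
cec_and_base_saturation <- function(Ca, Mg, K, acidity) {
  stopifnot(is.numeric(Ca), is.numeric(Mg), is.numeric(K), is.numeric(acidity))
  if (any(c(Ca, Mg, K, acidity) < 0)) stop("inputs must be nonnegative")
  cec <- Ca + Mg + K + acidity
  if (any(cec == 0)) stop("undefined saturation: CEC is zero")
  list(cec = cec, base_saturation = 100 * (Ca + Mg + K) / cec)
}
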