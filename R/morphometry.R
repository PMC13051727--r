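#' Caliper tumor volume
#'
#' Ellipsoid-style caliper estimate `V = 0.5 * L * W * H`, with length,
#' width and height in centimeters, giving cubic centimeters. Vectorized.
#'
#' @param L,W,H Caliper dimensions in cm (non-negative).
#' @return Volume in cm^3.
#' @examples
#' tumor_volume(1, 2, 3)  # 3
#' @export
tumor_volume <- function(L, W, H) {
  if (any(c(L, W, H) < 0)) stop("caliper dimensions must be non-negative")
  0.5 * L * W * H
}

#' Tumor density from explant mass and caliper volume
#'
#' `D = M / V` with mass in grams and volume in cm^3.
#'
#' @param mass Explant mass in g.
#' @param volume Volume in cm^3 (strictly positive).
#' @return Density in g/cm^3.
#' @export
tumor_density <- function(mass, volume) {
  if (any(volume <= 0)) stop("`volume` must be strictly positive")
  mass / volume
}

#' Wound-closure curve from traced areas
#'
#' Converts a series of traced wound areas (e.g. from digital photographs
#' measured in ImageJ) to the fraction of the original wound remaining
#' open, and finds the day of closure: the first day whose area is at or
#' below `closure_epsilon` (default 0, i.e. strictly complete closure).
#'
#' @param day Integer vector of measurement days; day 0 must be present.
#' @param area Wound areas (mm^2) matching `day`; area on day 0 must be
#'   positive.
#' @param closure_epsilon Area at or below which the wound counts as
#'   closed (default 0).
#' @return List with `series` (data frame day, area, fraction_open,
#'   ordered by day) and `closure_day` (`NA` if never closed).
#' @examples
#' wound_closure(c(0, 4, 11), c(28.3, 14.15, 0))$closure_day  # 11
#' @export
wound_closure <- function(day, area, closure_epsilon = 0) {
  if (length(day) != length(area)) stop("`day` and `area` lengths differ")
  o <- order(day)
  day <- day[o]
  area <- area[o]
  if (day[1] != 0) stop("the series must include day 0")
  if (area[1] <= 0) stop("day-0 wound area must be positive")
  if (any(area < 0)) stop("areas must be non-negative")
  frac <- area / area[1]
  closed <- which(area <= closure_epsilon)
  list(series = data.frame(day = day, area = area, fraction_open = frac),
       closure_day = if (length(closed)) day[closed[1]] else NA_real_)
}

#' Reference-gene-normalized relative expression
#'
#' Delta-Ct quantification: expression of a target gene relative to a
#' reference (housekeeping) gene, `2^-(dCt - calibrator_delta)` with
#' `dCt = ct_target - ct_reference`. With the default `calibrator_delta
#' = 0` this is plain `2^-dCt`; passing the delta-Ct of a calibrator
#' sample yields the ddCt convention.
#'
#' @param ct_target,ct_reference Finite Ct values (vectorized).
#' @param calibrator_delta Optional calibrator delta-Ct (default 0).
#' @return Relative expression (1 when target equals reference).
#' @examples
#' relative_expression(25, 25)  # 1
#' relative_expression(26, 25)  # 0.5
#' @export
relative_expression <- function(ct_target, ct_reference, calibrator_delta = 0) {
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_reference)))
    stop("Ct values must be finite")
  2^(-((ct_target - ct_reference) - calibrator_delta))
}
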