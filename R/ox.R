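#' Combined oxidant capacity (Ox) of NO2 and O3
#'
#' Computes the redox-weighted average of nitrogen dioxide and ozone
#' concentrations,
#' \deqn{O_x = (1.07 \cdot NO_2 + 2.075 \cdot O_3) / 3.145,}
#' where the weights are the redox potentials of the two gases and the
#' denominator is their sum, so that `Ox` is a convex combination of the two
#' inputs and is expressed in ppb when both inputs are in ppb.
#'
#' Every Ox value in the package flows through this function: the synthetic
#' pollutant generator, the exposure assembler and the reporting layer all
#' call it rather than re-deriving the weights.
#'
#' @param no2 Numeric vector of NO2 concentrations (ppb), non-negative.
#' @param o3 Numeric vector of O3 concentrations (ppb), non-negative.
#'   Recycled against `no2` if either is length one.
#' @return Numeric vector of Ox concentrations (ppb).
#' @examples
#' compute_ox(11.47, 38.29) # mean NO2 and O3 give mean Ox ~= 29.17
#' compute_ox(10, 10)       # equal inputs are a fixed point
#' @export
compute_ox <- function(no2, o3) {
  if (length(no2) == 1L) no2 <- rep_len(no2, length(o3))
  if (length(o3) == 1L) o3 <- rep_len(o3, length(no2))
  if (length(no2) != length(o3)) {
    stop("`no2` and `o3` must have the same length (or be scalar)")
  }
  if (anyNA(no2) || anyNA(o3)) stop("`no2`/`o3` contain missing values")
  if (any(no2 < 0) || any(o3 < 0)) {
    stop("negative concentrations are not allowed in compute_ox()")
  }
  (OX_WEIGHT_NO2 * no2 + OX_WEIGHT_O3 * o3) / (OX_WEIGHT_NO2 + OX_WEIGHT_O3)
}

# Redox potentials used as weights; their sum (3.145) is the denominator.
OX_WEIGHT_NO2 <- 1.07
OX_WEIGHT_O3 <- 2.075

#' Flag regions whose Ox concentration exceeds a threshold
#'
#' Marks regions with oxidant capacity strictly above a threshold (default
#' 23 ppb, the approximate concentration below which Ox does not appear to
#' modify PM2.5 mortality risk). Regions above the threshold are those where
#' reductions in oxidant gases are expected to reduce the chronic health
#' impact of PM2.5 even at unchanged mass concentrations.
#'
#' @param ox Numeric vector of region-level Ox concentrations (ppb).
#' @param threshold Threshold in ppb; strict inequality (`ox > threshold`).
#' @return A list with `flagged` (logical vector), `n_flagged`, `n` and
#'   `fraction` flagged.
#' @export
flag_above_threshold <- function(ox, threshold = 23.0) {
  stopifnot(is.numeric(ox), is.numeric(threshold), length(threshold) == 1L)
  flagged <- !is.na(ox) & ox > threshold
  list(
    flagged = flagged,
    n_flagged = sum(flagged),
    n = length(ox),
    fraction = if (length(ox)) sum(flagged) / length(ox) else NA_real_,
    threshold = threshold
  )
}
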