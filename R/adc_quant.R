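#' Apparent diffusion coefficient map from two b-value volumes
#'
#' Exact two-point log-linear solution
#' \eqn{ADC = \ln(S_{low}/S_{high}) / (b_{high} - b_{low})}, which equals the
#' least-squares line through the two (b, ln S) points. Voxels with
#' non-positive signal inside the mask are set `NA` (excluded from features
#' downstream); negative ADC values arising from noise are retained, not
#' clipped.
#'
#' @param s_low,s_high 3-D signal volumes at the low and high b-value.
#' @param b_low,b_high Diffusion weightings in s/mm^2, `b_high > b_low >= 0`.
#' @param brain_mask Logical 3-D array; voxels outside are `NA`.
#' @return ADC volume in mm^2/s, with attribute `units = "mm^2/s"` and the
#'   number of excluded voxels in `"n_excluded"`.
#' @export
compute_adc <- function(s_low, s_high, b_low, b_high, brain_mask = NULL) {
  if (!identical(dim(s_low), dim(s_high)))
    stop("the two b-value volumes must have identical shape")
  if (b_high <= b_low || b_low < 0)
    stop("b-values must satisfy b_high > b_low >= 0")
  if (is.null(brain_mask)) brain_mask <- array(TRUE, dim(s_low))
  if (!identical(dim(brain_mask), dim(s_low)))
    stop("brain_mask shape does not match the volumes")
  out <- array(NA_real_, dim(s_low))
  ok <- brain_mask & s_low > 0 & s_high > 0
  out[ok] <- log(s_low[ok] / s_high[ok]) / (b_high - b_low)
  attr(out, "units") <- "mm^2/s"
  attr(out, "n_excluded") <- sum(brain_mask & !ok)
  out
}
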