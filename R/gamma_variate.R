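#' Gamma-variate concentration curve
#'
#' The canonical first-pass bolus model used in DSC-MRI:
#' \deqn{C(t) = A (t - t_0)^\alpha e^{-(t - t_0)/\beta}, \quad t > t_0}
#' and 0 at or before the arrival time `t0`.
#'
#' @param t Time grid in seconds.
#' @param A Amplitude (concentration units, here s^-1 as a Delta-R2*).
#' @param alpha Dimensionless shape parameter, > 0.
#' @param beta Time scale in seconds, > 0.
#' @param t0 Bolus arrival time in seconds.
#' @return Concentration at each `t`.
#' @export
gamma_variate <- function(t, A, alpha, beta, t0) {
  if (alpha <= 0 || beta <= 0)
    stop("gamma-variate shape and scale must be positive")
  dt <- t - t0
  out <- numeric(length(t))
  pos <- dt > 0
  out[pos] <- A * dt[pos]^alpha * exp(-dt[pos] / beta)
  out
}

#' Closed-form integral of the gamma-variate curve
#'
#' \eqn{\int_{t_0}^{\infty} A (t-t_0)^\alpha e^{-(t-t_0)/\beta} dt
#'   = A \beta^{\alpha+1} \Gamma(\alpha+1)}.
#'
#' @inheritParams gamma_variate
#' @return Scalar integral (concentration x time).
#' @export
gamma_variate_integral <- function(A, alpha, beta) {
  if (alpha <= 0 || beta <= 0)
    stop("gamma-variate shape and scale must be positive")
  A * beta^(alpha + 1) * gamma(alpha + 1)
}
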