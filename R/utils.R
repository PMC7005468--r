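#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded package functions do
#' not disturb the caller's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

#' Cumulative trapezoidal integral
#'
#' @param t Sample points (strictly increasing).
#' @param y Values at `t`.
#' @return Vector of running integrals, same length as `t`, starting at 0.
#' @keywords internal
cumtrapz1 <- function(t, y) {
  n <- length(t)
  if (length(y) != n) stop("'t' and 'y' must have equal length")
  if (n < 2L) return(rep(0, n))
  c(0, cumsum(diff(t) * (y[-1] + y[-n]) / 2))
}

trapz1 <- function(t, y) {
  n <- length(t)
  if (n < 2L) return(0)
  sum(diff(t) * (y[-1] + y[-n]) / 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The three tumour-type labels used throughout the package
#' @return Character vector of class labels in canonical order.
#' @export
tumour_classes <- function() {
  c("pilocytic_astrocytoma", "medulloblastoma", "ependymoma")
}

#' Map tumour-type labels to the binary grade task
#'
#' Pilocytic astrocytoma is low grade; medulloblastoma and ependymoma are
#' high grade.
#'
#' @param labels Character vector (or factor) of tumour-type labels.
#' @return Factor with levels `low`, `high`.
#' @export
grade_task_labels <- function(labels) {
  labels <- as.character(labels)
  known <- tumour_classes()
  bad <- setdiff(unique(labels), known)
  if (length(bad))
    stop("unknown tumour label(s): ", paste(bad, collapse = ", "))
  factor(ifelse(labels == "pilocytic_astrocytoma", "low", "high"),
         levels = c("low", "high"))
}
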