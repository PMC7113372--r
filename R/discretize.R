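# Tertile discretization of expression/PSI vectors and the eight-bin
# sample retention rule.

#' Tertile-discretize a vector
#'
#' Non-missing values are rank-ordered ascending (ties broken stably by
#' original position); the lowest `floor(n/3)` become label `0` (lower
#' tertile), the highest `floor(n/3)` become label `1` (upper tertile), and
#' the remainder -- the middle tertile -- together with missing inputs are
#' labelled `NA` (the NULL bin).
#'
#' @param values numeric vector, `NA` for missing.
#' @return Integer vector of the same length with entries in
#'   `{0L, 1L, NA}`.
#' @export
tertileDiscretize <- function(values) {
  obs <- which(!is.na(values))
  n <- length(obs)
  if (n < 3)
    stop("tertile discretization requires at least 3 non-missing values")
  k <- n %/% 3
  ord <- obs[order(values[obs], obs)]
  labels <- rep(NA_integer_, length(values))
  labels[ord[seq_len(k)]] <- 0L
  labels[ord[seq.int(n - k + 1, n)]] <- 1L
  labels
}

#' Samples retained for the interaction fit
#'
#' A sample is retained iff none of the three discretized variables (RBP
#' expression, modulator expression, target PSI) is in the NULL bin, so the
#' joint label space of retained samples has at most 2^3 = 8 cells.
#'
#' @param d_rbp,d_mod,d_target integer label vectors from
#'   [tertileDiscretize()], equal length.
#' @return Logical mask of retained samples.
#' @export
retainedMask <- function(d_rbp, d_mod, d_target) {
  if (length(d_rbp) != length(d_mod) || length(d_mod) != length(d_target))
    stop("label vectors must have equal length")
  !is.na(d_rbp) & !is.na(d_mod) & !is.na(d_target)
}
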