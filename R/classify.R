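# Conditional-correlation classification: Pearson correlation between RBP
# expression and target PSI within modulator-low and modulator-high sample
# groups, and the six-category rule table.

#' Group-wise RBP-PSI correlations
#'
#' Samples are ordered by modulator expression (ties broken stably by
#' position); the bottom `floor(frac * n)` form the modulator-low group and
#' the top `floor(frac * n)` the modulator-high group.  Within each group,
#' samples with missing PSI are dropped and the Pearson correlation between
#' RBP expression and target PSI is computed on the raw (continuous)
#' values, with a two-sided correlation-test p-value.
#'
#' @param rbp_expr,target_psi,modulator_expr aligned numeric vectors
#'   (`target_psi` may contain `NA`).
#' @param frac fraction of samples per group (default 1/3, i.e. bottom/top
#'   33%).
#' @return A list of class `"GroupCorrelation"`: `pcc_low`, `p_low`,
#'   `n_low`, `pcc_high`, `p_high`, `n_high`, `delta` (`|pcc_high| -
#'   |pcc_low|`).
#' @export
groupCorrelations <- function(rbp_expr, target_psi, modulator_expr,
                              frac = 1/3) {
  n <- length(modulator_expr)
  stopifnot(length(rbp_expr) == n, length(target_psi) == n)
  g <- floor(frac * n)
  if (g < 3)
    stop("need at least 3 samples per modulator group")
  ord <- order(modulator_expr, seq_len(n))
  one_group <- function(idx, label) {
    idx <- idx[!is.na(target_psi[idx])]
    if (length(idx) < 3)
      stop("fewer than 3 usable samples in modulator-", label, " group")
    x <- rbp_expr[idx]; y <- target_psi[idx]
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      stop("constant values in modulator-", label,
           " group: correlation undefined")
    ct <- stats::cor.test(x, y, method = "pearson")
    list(pcc = unname(ct$estimate), p = ct$p.value, n = length(idx))
  }
  lo <- one_group(ord[seq_len(g)], "low")
  hi <- one_group(ord[seq.int(n - g + 1, n)], "high")
  out <- list(pcc_low = lo$pcc, p_low = lo$p, n_low = lo$n,
              pcc_high = hi$pcc, p_high = hi$p, n_high = hi$n,
              delta = abs(hi$pcc) - abs(lo$pcc))
  class(out) <- "GroupCorrelation"
  out
}

#' @export
print.GroupCorrelation <- function(x, ...) {
  cat(sprintf(
    "GroupCorrelation: low r = %.3f (p = %.3g, n = %d); high r = %.3f (p = %.3g, n = %d); delta |r| = %.3f\n",
    x$pcc_low, x$p_low, x$n_low, x$pcc_high, x$p_high, x$n_high, x$delta))
  invisible(x)
}

#' Construct a GroupCorrelation from known values
#'
#' Useful for classifying published correlation pairs directly.
#'
#' @param pcc_low,p_low,pcc_high,p_high group correlations and their
#'   p-values.
#' @param n_low,n_high group sizes (informational).
#' @return A `"GroupCorrelation"` list.
#' @export
groupCorrelation <- function(pcc_low, p_low, pcc_high, p_high,
                             n_low = NA_integer_, n_high = NA_integer_) {
  stopifnot(abs(pcc_low) <= 1, abs(pcc_high) <= 1,
            p_low >= 0, p_low <= 1, p_high >= 0, p_high <= 1)
  out <- list(pcc_low = pcc_low, p_low = p_low, n_low = n_low,
              pcc_high = pcc_high, p_high = p_high, n_high = n_high,
              delta = abs(pcc_high) - abs(pcc_low))
  class(out) <- "GroupCorrelation"
  out
}

#' Classify the modulation mode of a triplet
#'
#' Applies the six-category rule table to the group-wise correlations.
#' With `sig_low = (p_low <= alpha)` and `sig_high = (p_high <= alpha)`:
#' \itemize{
#'   \item both significant, opposite signs: low negative / high positive
#'     is ExonEI (exclusion-to-inclusion inversion); low positive / high
#'     negative is ExonIE;
#'   \item both significant, both negative (exon exclusion):
#'     `|pcc_low| > |pcc_high|` attenuates it (AEE), otherwise enhances it
#'     (EEE);
#'   \item both significant, both positive (exon inclusion):
#'     `|pcc_low| > |pcc_high|` is AEI, otherwise EEI;
#'   \item only the low group significant: negative is AEE, positive AEI
#'     (the correlation is lost as the modulator rises);
#'   \item only the high group significant: negative is EEE, positive EEI
#'     (the correlation appears as the modulator rises);
#'   \item neither significant: UNCLASSIFIED.
#' }
#' Inversions require both correlations significant so that a sign flip is
#' never called from a noise-level point estimate.
#'
#' @param gc a `"GroupCorrelation"` (see [groupCorrelations()] /
#'   [groupCorrelation()]).
#' @param alpha significance cutoff on the correlation-test p-values
#'   (default 0.05).
#' @return A list of class `"ModulationCall"`: `category` (one of AEE, AEI,
#'   EEE, EEI, ExonIE, ExonEI, UNCLASSIFIED), `basis` (the input), `alpha`.
#' @export
classifyModulation <- function(gc, alpha = 0.05) {
  sig_low <- gc$p_low <= alpha
  sig_high <- gc$p_high <= alpha
  lo <- gc$pcc_low
  hi <- gc$pcc_high
  category <- if (sig_low && sig_high) {
    if (lo < 0 && hi > 0) "ExonEI"
    else if (lo > 0 && hi < 0) "ExonIE"
    else if (lo < 0 && hi < 0) { if (abs(lo) > abs(hi)) "AEE" else "EEE" }
    else if (lo > 0 && hi > 0) { if (abs(lo) > abs(hi)) "AEI" else "EEI" }
    else "UNCLASSIFIED"                     # a zero correlation has no sign
  } else if (sig_low) {
    if (lo < 0) "AEE" else if (lo > 0) "AEI" else "UNCLASSIFIED"
  } else if (sig_high) {
    if (hi < 0) "EEE" else if (hi > 0) "EEI" else "UNCLASSIFIED"
  } else "UNCLASSIFIED"
  out <- list(category = category, basis = gc, alpha = alpha)
  class(out) <- "ModulationCall"
  out
}

#' @export
print.ModulationCall <- function(x, ...) {
  cat(sprintf("ModulationCall: %s (alpha = %g)\n", x$category, x$alpha))
  invisible(x)
}

#' Annotate screened triplets with group correlations and categories
#'
#' For each triplet record, computes [groupCorrelations()] on the raw
#' log-expression and PSI vectors and assigns a category with
#' [classifyModulation()].  Records whose groups are degenerate (too few
#' usable samples, constant values) become UNCLASSIFIED with the failure
#' reason recorded.
#'
#' @param records data.frame from [screenTriplets()].
#' @param expr an [ExpressionMatrix-class].
#' @param psi a [PsiMatrix-class] aligned with `expr`.
#' @param alpha significance cutoff for the category rules (default 0.05).
#' @param frac fraction of samples per modulator group (default 1/3).
#' @return `records` with added columns `pcc_low`, `p_low`, `n_low`,
#'   `pcc_high`, `p_high`, `n_high`, `delta`, `category`, `reason`.
#' @export
annotateTriplets <- function(records, expr, psi, alpha = 0.05, frac = 1/3) {
  n <- nrow(records)
  add <- data.frame(pcc_low = rep(NA_real_, n), p_low = rep(NA_real_, n),
                    n_low = rep(NA_integer_, n),
                    pcc_high = rep(NA_real_, n), p_high = rep(NA_real_, n),
                    n_high = rep(NA_integer_, n), delta = rep(NA_real_, n),
                    category = rep("UNCLASSIFIED", n),
                    reason = rep("", n), stringsAsFactors = FALSE)
  lx <- log2(expr@.Data + 1)
  for (i in seq_len(n)) {
    gc <- tryCatch(
      groupCorrelations(lx[records$rbp[i], ],
                        psi@.Data[records$event[i], ],
                        lx[records$modulator[i], ], frac = frac),
      error = function(e) e)
    if (inherits(gc, "error")) {
      add$reason[i] <- conditionMessage(gc)
      next
    }
    add$pcc_low[i] <- gc$pcc_low; add$p_low[i] <- gc$p_low
    add$n_low[i] <- gc$n_low; add$pcc_high[i] <- gc$pcc_high
    add$p_high[i] <- gc$p_high; add$n_high[i] <- gc$n_high
    add$delta[i] <- gc$delta
    add$category[i] <- classifyModulation(gc, alpha = alpha)$category
  }
  out <- cbind(records, add)
  rownames(out) <- NULL
  # keep screen attributes through the annotation step
  attr(out, "funnel") <- attr(records, "funnel")
  attr(out, "skipped") <- attr(records, "skipped")
  out
}
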