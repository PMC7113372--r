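# Cohort eligibility filters: gene expression, splicing-event quality, and
# the RBP/modulator statistical-independence screen.

#' Filter genes by expression level
#'
#' Keeps genes whose mean `log2(CPM + 1)` across samples reaches
#' `min_log2_cpm` (the pseudocount avoids log of zero).  Order is preserved.
#'
#' @param expr an [ExpressionMatrix-class].
#' @param cfg a [FilterConfig-class].
#' @return Character vector of retained gene ids, in input order.
#' @export
filterGenesByExpression <- function(expr, cfg = filterConfig()) {
  means <- rowMeans(log2(expr@.Data + 1))
  keep <- geneIds(expr)[means >= cfg@min_log2_cpm]
  if (!length(keep))
    warning("no genes pass the expression filter")
  keep
}

#' Coefficient of variation of a PSI vector
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean,
#' computed over non-missing values.
#'
#' @param values numeric vector with `NA` for missing.
#' @return The CV, a single number.
#' @export
coefficientOfVariation <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 2)
    stop("CV requires at least 2 non-missing values")
  m <- mean(v)
  if (m <= 0)
    stop("CV is undefined for non-positive mean")
  stats::sd(v) / m
}

#' Filter splicing events by PSI quality
#'
#' Keeps events satisfying all of: PSI strictly above `min_psi` in at least
#' `min_samples_above_min_psi` samples; at least `min_non_missing`
#' non-missing values; coefficient of variation of PSI strictly above
#' `min_cv`.  Events whose CV is undefined (fewer than 2 non-missing values
#' or zero mean) are removed.
#'
#' @param psi a [PsiMatrix-class].
#' @param cfg a [FilterConfig-class].
#' @return Character vector of retained event ids, in input order.
#' @export
filterEvents <- function(psi, cfg = filterConfig()) {
  v <- psi@.Data
  n_above <- rowSums(v > cfg@min_psi, na.rm = TRUE)
  n_obs <- rowSums(!is.na(v))
  cv <- vapply(seq_len(nrow(v)), function(i) {
    tryCatch(coefficientOfVariation(v[i, ]), error = function(e) NA_real_)
  }, numeric(1))
  keep <- n_above >= cfg@min_samples_above_min_psi &
    n_obs >= cfg@min_non_missing &
    !is.na(cv) & cv > cfg@min_cv
  eventIds(psi)[keep]
}

#' RBP/modulator independence screen
#'
#' Returns the (rbp, modulator) pairs whose expression profiles are
#' statistically independent: by default, pairs with
#' `|Pearson r| <= max_abs_pcc_independence` on `log2(CPM + 1)` values.
#' With `independence_method = "pvalue"` a pair is kept when the two-sided
#' correlation-test p-value exceeds `independence_alpha`.  Self-pairs are
#' always excluded.
#'
#' @param expr an [ExpressionMatrix-class].
#' @param rbp_ids character vector of RBP gene ids (present in `expr`).
#' @param candidate_ids character vector of candidate modulator gene ids.
#' @param cfg a [FilterConfig-class].
#' @return data.frame with columns `rbp`, `modulator`, `pcc`.
#' @export
independentPairs <- function(expr, rbp_ids, candidate_ids,
                             cfg = filterConfig()) {
  missing <- setdiff(c(rbp_ids, candidate_ids), geneIds(expr))
  if (length(missing))
    stop("gene ids absent from expression matrix: ",
         paste(head(missing, 5), collapse = ", "))
  lx <- log2(expr@.Data + 1)
  r_mat <- stats::cor(t(lx[rbp_ids, , drop = FALSE]),
                      t(lx[candidate_ids, , drop = FALSE]))
  pairs <- expand.grid(rbp = rbp_ids, modulator = candidate_ids,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pairs$pcc <- as.vector(r_mat)
  pairs <- pairs[pairs$rbp != pairs$modulator, , drop = FALSE]
  if (cfg@independence_method == "pcc") {
    keep <- abs(pairs$pcc) <= cfg@max_abs_pcc_independence
  } else {
    n <- ncol(expr)
    tt <- abs(pairs$pcc) * sqrt((n - 2) / pmax(1 - pairs$pcc^2, .Machine$double.eps))
    pval <- 2 * stats::pt(tt, df = n - 2, lower.tail = FALSE)
    keep <- pval > cfg@independence_alpha
  }
  keep <- !is.na(pairs$pcc) & keep   # constant profiles have no defined r
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
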