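# The interaction screen: per-triplet estimation of the interaction
# coefficient beta3 of
#   Y_target = beta0 + beta1 X_rbp + beta2 X_mod + beta3 X_rbp X_mod + eps
# on the tertile-discretized design, its test, and genome-scale selection
# under Benjamini-Hochberg FDR control.

# Core estimator shared by interactionFit() and screenTriplets(): given the
# four (rbp, mod) cell sizes and upper-tertile target counts, the
# coefficients are differences in observed inclusion proportions; on this
# saturated 2x2 design they coincide exactly with the OLS coefficients of
# the model above.
.fitCells <- function(n, s) {
  # n, s indexed as (r, m) = (0,0), (0,1), (1,0), (1,1)
  p <- s / n
  beta0 <- p[1]
  beta1 <- p[3] - p[1]
  beta2 <- p[2] - p[1]
  beta3 <- p[4] - p[3] - p[2] + p[1]
  se3 <- sqrt(sum(p * (1 - p) / n))
  if (se3 == 0) {
    z <- if (beta3 == 0) 0 else sign(beta3) * Inf
    pval <- if (beta3 == 0) 1 else 0
    degenerate <- beta3 != 0
  } else {
    z <- beta3 / se3
    pval <- 2 * stats::pnorm(-abs(z))
    degenerate <- FALSE
  }
  list(beta0 = beta0, beta1 = beta1, beta2 = beta2, beta3 = beta3,
       se3 = se3, z = z, p = pval, degenerate = degenerate)
}

.cellCounts <- function(d_rbp, d_mod, d_target, mask) {
  idx <- which(mask)
  r <- d_rbp[idx]; m <- d_mod[idx]; t <- d_target[idx]
  cell <- m + 2L * r + 1L                 # 1:(0,0) 2:(0,1) 3:(1,0) 4:(1,1)
  list(n = tabulate(cell, 4L), s = tabulate(cell[t == 1L], 4L))
}

#' Fit the interaction model on one discretized triplet
#'
#' Estimates the coefficients from differences in observed inclusion
#' proportions: with `p_rm` the proportion of upper-tertile-PSI samples in
#' cell `(r, m)` of the (rbp label x modulator label) table,
#' `beta3 = p_11 - p_10 - p_01 + p_00`, tested against zero with a
#' binomial-variance normal statistic
#' `z = beta3 / sqrt(sum p_rm (1 - p_rm) / n_rm)`.
#'
#' @param d_rbp,d_mod,d_target integer labels from [tertileDiscretize()].
#' @param mask logical retention mask, by default
#'   `retainedMask(d_rbp, d_mod, d_target)`.
#' @param min_cell_count minimum retained samples per cell; an undersized
#'   cell aborts with an error of class `spliceMod_undersized_cell`.
#' @return A list of class `"InteractionFit"`: `beta0..beta3`, `se3`, `z`,
#'   `p`, `n_retained`, `cell_counts` (2x2, rbp x modulator) and
#'   `degenerate` (`TRUE` when `se3 = 0` with a non-zero `beta3`).
#' @export
interactionFit <- function(d_rbp, d_mod, d_target,
                           mask = retainedMask(d_rbp, d_mod, d_target),
                           min_cell_count = 5L) {
  cc <- .cellCounts(d_rbp, d_mod, d_target, mask)
  if (any(cc$n < min_cell_count))
    stop(structure(class = c("spliceMod_undersized_cell", "error", "condition"),
                   list(message = sprintf(
                     "undersized design cell (min %d, need >= %d)",
                     min(cc$n), min_cell_count), call = sys.call(-1))))
  fit <- .fitCells(cc$n, cc$s)
  fit$n_retained <- sum(cc$n)
  fit$cell_counts <- matrix(cc$n, 2, 2, byrow = TRUE,
                            dimnames = list(rbp = c("0", "1"),
                                            mod = c("0", "1")))
  class(fit) <- "InteractionFit"
  fit
}

#' @export
print.InteractionFit <- function(x, ...) {
  cat(sprintf("InteractionFit: beta3 = %.4f (se %.4f, z = %.2f, p = %.3g), n = %d\n",
              x$beta3, x$se3, x$z, x$p, x$n_retained))
  invisible(x)
}

#' Continuous OLS variant of the interaction fit
#'
#' Ordinary least squares of the interaction model on raw values (log2(CPM
#' + 1) expression, continuous PSI) over samples with non-missing PSI, with
#' a t-test on the interaction coefficient.
#'
#' @param x_rbp,x_mod,y numeric vectors (PSI `y` may contain `NA`).
#' @return A list of class `"InteractionFit"` (with `se3`, `z` = t
#'   statistic, `p`, `n_retained`).
#' @export
interactionFitOLS <- function(x_rbp, x_mod, y) {
  ok <- !is.na(y) & !is.na(x_rbp) & !is.na(x_mod)
  fit <- stats::lm(y[ok] ~ x_rbp[ok] * x_mod[ok])
  sm <- summary(fit)$coefficients
  out <- list(beta0 = unname(coef(fit)[1]), beta1 = unname(coef(fit)[2]),
              beta2 = unname(coef(fit)[3]), beta3 = unname(coef(fit)[4]),
              se3 = sm[4, 2], z = sm[4, 3], p = sm[4, 4],
              n_retained = sum(ok), cell_counts = NULL, degenerate = FALSE)
  class(out) <- "InteractionFit"
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up adjusted values with monotonicity enforcement (thin
#' wrapper over `stats::p.adjust(method = "BH")`).
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values.
#' @export
bhAdjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Screen all candidate triplets for an interaction effect
#'
#' Enumerates (modulator, rbp, event) triplets over the target map and the
#' candidate (rbp, modulator) pairs, discretizes each variable by tertiles,
#' fits the interaction model on the retained eight-bin samples, adjusts
#' p-values jointly across all tested triplets with Benjamini-Hochberg, and
#' selects triplets with `q <= fdr`.
#'
#' @param expr an [ExpressionMatrix-class] holding RBP and modulator
#'   expression.
#' @param psi a [PsiMatrix-class] with samples aligned to `expr`.
#' @param target_map an [RbpTargetMap-class].
#' @param pairs candidate pairs: a data.frame with columns `rbp` and
#'   `modulator` (e.g. from [independentPairs()]), or a character vector of
#'   modulator ids to pair with every RBP of the map (self-pairs dropped).
#' @param cfg a [ScreenConfig-class].
#' @param all when `TRUE` return every tested triplet (with a `selected`
#'   column) instead of only the selected ones.
#' @return data.frame of triplets with columns `modulator`, `rbp`, `event`,
#'   `beta0..beta3`, `se3`, `z`, `p`, `q`, `n_retained`, `selected`;
#'   selected rows are sorted by `q` then decreasing `|beta3|`.  Attributes:
#'   `funnel` (named stage counts), `skipped` (data.frame of skipped
#'   triplets with reasons).
#' @export
screenTriplets <- function(expr, psi, target_map, pairs,
                           cfg = screenConfig(), all = FALSE) {
  map <- targetTable(target_map)
  if (is.character(pairs)) {
    pairs <- expand.grid(rbp = rbps(target_map), modulator = pairs,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$rbp != pairs$modulator, , drop = FALSE]
  }
  stopifnot(all(c("rbp", "modulator") %in% names(pairs)))
  if ("event_id" %in% names(pairs)) {
    # per-event candidate sets: each row is already one triplet
    trip <- merge(pairs[c("rbp", "modulator", "event_id")],
                  map[c("rbp", "event_id")],
                  by = c("rbp", "event_id"), sort = FALSE)
  } else {
    # for each (rbp, modulator) pair, all events bound by the rbp
    trip <- merge(pairs[c("rbp", "modulator")], map[c("rbp", "event_id")],
                  by = "rbp", sort = FALSE)
  }
  funnel <- c(candidate_pairs = nrow(pairs), tested = 0L, skipped = 0L,
              selected = 0L)
  empty <- data.frame(modulator = character(), rbp = character(),
                      event = character(), beta0 = numeric(),
                      beta1 = numeric(), beta2 = numeric(),
                      beta3 = numeric(), se3 = numeric(), z = numeric(),
                      p = numeric(), q = numeric(), n_retained = integer(),
                      selected = logical(), stringsAsFactors = FALSE)
  if (!nrow(trip)) {
    attr(empty, "funnel") <- funnel
    attr(empty, "skipped") <- data.frame(modulator = character(),
                                         rbp = character(),
                                         event = character(),
                                         reason = character())
    return(empty)
  }
  genes <- unique(c(trip$rbp, trip$modulator))
  events <- unique(trip$event_id)
  gene_lab <- t(apply(expr@.Data[genes, , drop = FALSE], 1,
                      tertileDiscretize))
  event_lab <- t(apply(psi@.Data[events, , drop = FALSE], 1,
                       tertileDiscretize))
  n_t <- nrow(trip)
  use_ols <- cfg@estimator == "continuous-ols"
  if (use_ols) {
    lx <- log2(expr@.Data[genes, , drop = FALSE] + 1)
    py <- psi@.Data[events, , drop = FALSE]
  }
  cols <- list(beta0 = numeric(n_t), beta1 = numeric(n_t),
               beta2 = numeric(n_t), beta3 = numeric(n_t),
               se3 = numeric(n_t), z = numeric(n_t), p = numeric(n_t),
               n_retained = integer(n_t))
  reason <- character(n_t)
  ri <- match(trip$rbp, genes); mi <- match(trip$modulator, genes)
  ei <- match(trip$event_id, events)
  for (i in seq_len(n_t)) {
    if (use_ols) {
      fit <- interactionFitOLS(lx[ri[i], ], lx[mi[i], ], py[ei[i], ])
    } else {
      R <- gene_lab[ri[i], ]; M <- gene_lab[mi[i], ]; T <- event_lab[ei[i], ]
      cc <- .cellCounts(R, M, T, !is.na(R) & !is.na(M) & !is.na(T))
      if (any(cc$n < cfg@min_cell_count)) {
        reason[i] <- sprintf("undersized cell (min %d)", min(cc$n))
        next
      }
      fit <- .fitCells(cc$n, cc$s)
      fit$n_retained <- sum(cc$n)
      if (fit$degenerate) reason[i] <- "degenerate: se3 = 0 with beta3 != 0"
    }
    cols$beta0[i] <- fit$beta0; cols$beta1[i] <- fit$beta1
    cols$beta2[i] <- fit$beta2; cols$beta3[i] <- fit$beta3
    cols$se3[i] <- fit$se3; cols$z[i] <- fit$z; cols$p[i] <- fit$p
    cols$n_retained[i] <- fit$n_retained
  }
  skipped_mask <- startsWith(reason, "undersized")
  res <- data.frame(modulator = trip$modulator, rbp = trip$rbp,
                    event = trip$event_id, cols,
                    stringsAsFactors = FALSE)[!skipped_mask, , drop = FALSE]
  res$q <- bhAdjust(res$p)
  res$selected <- res$q <= cfg@fdr
  skipped <- data.frame(modulator = trip$modulator[skipped_mask],
                        rbp = trip$rbp[skipped_mask],
                        event = trip$event_id[skipped_mask],
                        reason = reason[skipped_mask],
                        stringsAsFactors = FALSE)
  funnel["tested"] <- nrow(res)
  funnel["skipped"] <- nrow(skipped)
  funnel["selected"] <- sum(res$selected)
  out <- if (all) res else {
    sel <- res[res$selected, , drop = FALSE]
    sel[order(sel$q, -abs(sel$beta3)), , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "funnel") <- funnel
  attr(out, "skipped") <- skipped
  out
}
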