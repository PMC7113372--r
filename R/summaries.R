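# Aggregation of annotated triplet tables: category counts, per-modulator
# target counts, the modulator x (rbp, event) pattern matrix, modulator
# clustering and the modulator co-expression matrix.

#' Category counts per RBP
#'
#' Exact multiset counts of the assigned categories, per RBP; the counts
#' sum to the number of input records.
#'
#' @param records annotated triplet data.frame (see [annotateTriplets()]).
#' @return data.frame with columns `rbp`, `category`, `n`.
#' @export
categoryCounts <- function(records) {
  if (!nrow(records))
    return(data.frame(rbp = character(), category = character(),
                      n = integer(), stringsAsFactors = FALSE))
  agg <- stats::aggregate(list(n = rep(1L, nrow(records))),
                          by = records[c("rbp", "category")], FUN = sum)
  agg <- agg[order(agg$rbp, agg$category), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Rank modulators by number of influenced splicing events
#'
#' Modulators are ranked by the number of distinct events they appear with
#' in the triplet table, descending; ties are broken lexicographically by
#' modulator id.
#'
#' @param records annotated triplet data.frame.
#' @param n how many to return (all if larger than the modulator count).
#' @return data.frame with columns `modulator`, `n_events`.
#' @export
topModulators <- function(records, n = 10L) {
  if (!nrow(records))
    return(data.frame(modulator = character(), n_events = integer(),
                      stringsAsFactors = FALSE))
  per <- unique(records[c("modulator", "event")])
  counts <- stats::aggregate(list(n_events = rep(1L, nrow(per))),
                             by = per["modulator"], FUN = sum)
  counts <- counts[order(-counts$n_events, counts$modulator), , drop = FALSE]
  rownames(counts) <- NULL
  head(counts, n)
}

#' Modulator regulation-pattern matrix
#'
#' Rows are modulators, columns are (rbp, event) pairs, cells hold the
#' category code: AEE = 1, AEI = 2, EEE = 3, EEI = 4, ExonIE = 5,
#' ExonEI = 6; absent (no triplet, or UNCLASSIFIED) = 0.  Rows and columns
#' are sorted lexicographically; duplicate (modulator, rbp, event) records
#' are an error.
#'
#' @param records annotated triplet data.frame.
#' @return Integer matrix with modulator rownames and `rbp|event` colnames.
#' @export
modulatorPatternMatrix <- function(records) {
  if (anyDuplicated(records[c("modulator", "rbp", "event")]))
    stop("duplicate (modulator, rbp, event) records")
  mods <- sort(unique(records$modulator))
  pairs <- sort(unique(paste(records$rbp, records$event, sep = "|")))
  m <- matrix(0L, length(mods), length(pairs),
              dimnames = list(mods, pairs))
  codes <- .CATEGORY_CODES[records$category]
  codes[is.na(codes)] <- 0L                      # UNCLASSIFIED -> absent
  m[cbind(match(records$modulator, mods),
          match(paste(records$rbp, records$event, sep = "|"), pairs))] <-
    as.integer(codes)
  m
}

#' Cluster modulators by regulation pattern
#'
#' Hierarchical agglomerative clustering (average linkage, Euclidean
#' distance) on the category-code rows of the pattern matrix, cut at `k`
#' clusters.  Deterministic given the input.
#'
#' @param pattern matrix from [modulatorPatternMatrix()].
#' @param k number of clusters (`1 <= k <= nrow(pattern)`).
#' @return Named integer vector of cluster labels, one per modulator.
#' @export
clusterModulators <- function(pattern, k) {
  if (k < 1 || k > nrow(pattern))
    stop("k must lie between 1 and the number of modulators (",
         nrow(pattern), ")")
  hc <- stats::hclust(stats::dist(pattern, method = "euclidean"),
                      method = "average")
  stats::cutree(hc, k = k)
}

#' Modulator co-expression matrix
#'
#' Pearson correlation matrix of the modulators' `log2(CPM + 1)`
#' expression profiles.
#'
#' @param expr an [ExpressionMatrix-class].
#' @param modulators character vector of modulator gene ids.
#' @return Symmetric correlation matrix.
#' @export
modulatorCorrelation <- function(expr, modulators) {
  missing <- setdiff(modulators, geneIds(expr))
  if (length(missing))
    stop("modulators absent from expression matrix: ",
         paste(head(missing, 5), collapse = ", "))
  stats::cor(t(log2(expr@.Data[modulators, , drop = FALSE] + 1)))
}
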