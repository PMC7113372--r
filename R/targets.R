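# From raw eCLIP peaks to an RBP -> skipped-exon-event target map:
# enrichment/p-value filter, replicate/cell-line union, +/- flank windows,
# interval overlap.

#' Filter peaks by enrichment and p-value
#'
#' Keeps peaks with fold enrichment at least `min_enrichment` (inclusive,
#' matching the log2FC >= 3 reading of the recommended eCLIP cutoff) and
#' p-value strictly below `max_pvalue`.
#'
#' @param peaks a `GRanges` from [readPeaks()] (possibly concatenated over
#'   files with `c()`).
#' @param cfg a [MappingConfig-class].
#' @return The retained peaks, in input order.
#' @export
filterPeaks <- function(peaks, cfg = mappingConfig()) {
  peaks[peaks$enrichment >= cfg@min_enrichment & peaks$pvalue < cfg@max_pvalue]
}

#' Merge peaks across replicates and cell lines per RBP
#'
#' Per RBP, takes the union of all peak intervals across replicates and
#' cell lines: overlapping or book-ended intervals are merged into maximal
#' intervals.  The number of contributing input peaks is kept per merged
#' interval.
#'
#' @param peaks a filtered peak `GRanges` with an `rbp` metadata column.
#' @param ignore_strand merge across strands (default `TRUE`); set `FALSE`
#'   for strand-specific mapping.
#' @return A `GRanges` of disjoint merged intervals with metadata columns
#'   `rbp` and `n_peaks`, sorted within each RBP.
#' @export
unionReplicates <- function(peaks, ignore_strand = TRUE) {
  merged_list <- lapply(S4Vectors::split(peaks, peaks$rbp), function(p) {
    m <- GenomicRanges::reduce(p, with.revmap = TRUE,
                               ignore.strand = ignore_strand)
    m$n_peaks <- S4Vectors::elementNROWS(m$revmap)
    m$revmap <- NULL
    m$rbp <- unique(p$rbp)
    m
  })
  out <- unlist(GenomicRanges::GRangesList(merged_list), use.names = FALSE)
  out
}

#' Flanked windows around skipped exons
#'
#' The binding window of an event runs from `flank_bp` bases upstream of
#' the skipped exon to `flank_bp` bases downstream of it (both strands
#' symmetric), clipped at position 1.
#'
#' @param events a [SpliceEventCatalog-class].
#' @param cfg a [MappingConfig-class] (uses `flank_bp`).
#' @return A `GRanges` of windows with an `event_id` metadata column.
#' @export
eventWindows <- function(events, cfg = mappingConfig()) {
  ev <- events@events
  if (!nrow(ev)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(event_id = character())
    return(gr)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = ev$chrom,
    ranges = IRanges::IRanges(start = pmax(1, ev$se_start - cfg@flank_bp),
                              end = ev$se_end + cfg@flank_bp),
    strand = ev$strand)
  gr$event_id <- ev$event_id
  gr
}

#' Map merged peaks onto event windows
#'
#' An event is a target of an RBP iff at least one of the RBP's merged peak
#' intervals overlaps the event's flanked window by at least one base on
#' the same chromosome.  Strand is ignored unless
#' `cfg@strand_specific = TRUE`.
#'
#' @param merged merged peak `GRanges` from [unionReplicates()].
#' @param events a [SpliceEventCatalog-class].
#' @param cfg a [MappingConfig-class].
#' @return An [RbpTargetMap-class]; `n_support` counts the merged intervals
#'   overlapping each window.
#' @export
mapTargets <- function(merged, events, cfg = mappingConfig()) {
  windows <- eventWindows(events, cfg)
  empty <- data.frame(rbp = character(), event_id = character(),
                      n_support = integer(), stringsAsFactors = FALSE)
  if (!length(merged) || !length(windows))
    return(RbpTargetMap(empty, events))
  peak_chr <- as.character(unique(GenomicRanges::seqnames(merged)))
  win_chr <- as.character(unique(GenomicRanges::seqnames(windows)))
  if (!length(intersect(peak_chr, win_chr))) {
    tab_p <- table(as.character(GenomicRanges::seqnames(merged)))
    tab_w <- table(as.character(GenomicRanges::seqnames(windows)))
    warning("no chromosome shared between peaks (",
            paste(sprintf("%s:%d", names(tab_p), as.integer(tab_p)),
                  collapse = ", "),
            ") and event windows (",
            paste(sprintf("%s:%d", names(tab_w), as.integer(tab_w)),
                  collapse = ", "), ")")
  }
  hits <- suppressWarnings(GenomicRanges::findOverlaps(
    merged, windows, minoverlap = 1L,
    ignore.strand = !cfg@strand_specific))
  if (!length(hits)) return(RbpTargetMap(empty, events))
  df <- data.frame(rbp = merged$rbp[S4Vectors::queryHits(hits)],
                   event_id = windows$event_id[S4Vectors::subjectHits(hits)],
                   stringsAsFactors = FALSE)
  agg <- stats::aggregate(list(n_support = rep(1L, nrow(df))),
                          by = df[c("rbp", "event_id")], FUN = sum)
  agg <- agg[order(agg$rbp, agg$event_id), , drop = FALSE]
  RbpTargetMap(agg, events)
}

#' Build a target map from raw peaks
#'
#' Convenience wrapper: [filterPeaks()] then [unionReplicates()] then
#' [mapTargets()].
#'
#' @param peaks raw peak `GRanges` (concatenated over files).
#' @param events a [SpliceEventCatalog-class].
#' @param cfg a [MappingConfig-class].
#' @return An [RbpTargetMap-class].
#' @export
buildTargetMap <- function(peaks, events, cfg = mappingConfig()) {
  kept <- filterPeaks(peaks, cfg)
  if (!length(kept))
    return(RbpTargetMap(data.frame(rbp = character(), event_id = character(),
                                   n_support = integer(),
                                   stringsAsFactors = FALSE), events))
  mapTargets(unionReplicates(kept, ignore_strand = !cfg@strand_specific),
             events, cfg)
}
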