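# Readers/writers for the tab-separated matrices, MISO-style event ids,
# eCLIP peak files and triplet result tables.

# ---- generic TSV matrix plumbing -------------------------------------------

# Read a feature-by-sample TSV: header = id column name + sample ids, first
# column = feature ids.  Body parsed cell-wise so a malformed cell can be
# reported with its row and column.
.readMatrixTsv <- function(path, missing_token = NULL) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           na.strings = character(0),
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2)
    stop("expected a tab-separated table with an id column and >= 1 sample")
  ids <- tab[[1]]
  if (anyDuplicated(ids))
    stop("duplicate feature ids: ",
         paste(unique(ids[duplicated(ids)])[1:min(3, sum(duplicated(ids)))],
               collapse = ", "))
  body <- as.matrix(tab[, -1, drop = FALSE])
  out <- matrix(NA_real_, nrow(body), ncol(body),
                dimnames = list(ids, colnames(body)))
  for (j in seq_len(ncol(body))) {
    cell <- body[, j]
    is_missing <- if (is.null(missing_token)) rep(FALSE, length(cell)) else
      cell == missing_token
    num <- suppressWarnings(as.numeric(cell))
    bad <- !is_missing & is.na(num)
    if (any(bad))
      stop(sprintf("malformed numeric cell at row '%s', column '%s': '%s'",
                   ids[which(bad)[1]], colnames(body)[j],
                   cell[which(bad)[1]]))
    num[is_missing] <- NA_real_
    out[, j] <- num
  }
  out
}

# Write with %.17g so that write/read round-trips are bit-identical.
.writeMatrixTsv <- function(values, path, id_name, missing_token = "NA") {
  fmt <- function(x) ifelse(is.na(x), missing_token, sprintf("%.17g", x))
  lines <- c(paste(c(id_name, colnames(values)), collapse = "\t"),
             vapply(seq_len(nrow(values)), function(i) {
               paste(c(rownames(values)[i], fmt(values[i, ])), collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene expression matrix (CPM) from TSV
#'
#' Expects a tab-separated table whose header row holds the sample ids and
#' whose first column holds the gene ids; the body must be non-negative
#' numbers.
#'
#' @param path path to the TSV file.
#' @return An [ExpressionMatrix-class].
#' @export
readExpressionMatrix <- function(path) {
  ExpressionMatrix(.readMatrixTsv(path))
}

#' Write an expression matrix to TSV
#'
#' @param expr an [ExpressionMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeExpressionMatrix <- function(expr, path) {
  .writeMatrixTsv(expr@.Data, path, "gene_id")
}

#' Read a PSI matrix from TSV
#'
#' @param path path to the TSV file (events x samples).
#' @param missing_token text marking a missing PSI estimate (default "NA").
#' @return A [PsiMatrix-class] with `NA` at missing entries.
#' @export
readPsiMatrix <- function(path, missing_token = "NA") {
  PsiMatrix(.readMatrixTsv(path, missing_token = missing_token))
}

#' Write a PSI matrix to TSV
#'
#' @param psi a [PsiMatrix-class].
#' @param path output path.
#' @param missing_token text written for missing entries (default "NA").
#' @return `path`, invisibly.
#' @export
writePsiMatrix <- function(psi, path, missing_token = "NA") {
  .writeMatrixTsv(psi@.Data, path, "event_id", missing_token = missing_token)
}

# ---- MISO-style skipped-exon event ids -------------------------------------

#' Parse MISO-style skipped-exon event ids
#'
#' An event id is three colon-delimited exon blocks joined by `"@"`, e.g.
#' `"chr11:57582866:57582972:+@chr11:57583387:57583473:+@chr11:57583769:57586652:+"`.
#' Blocks are coordinate-ascending; the middle block is the skipped exon
#' regardless of strand.  Whitespace around tokens is tolerated.
#' Coordinates are 1-based inclusive.
#'
#' @param ids character vector of event ids.
#' @return A [SpliceEventCatalog-class] with one record per id, in input
#'   order; `event_id` is the canonical (whitespace-free) serialization.
#' @export
parseEventId <- function(ids) {
  recs <- lapply(ids, function(id) {
    blocks <- strsplit(id, "@", fixed = TRUE)[[1]]
    if (length(blocks) != 3)
      stop(sprintf("event id must have exactly 3 exon blocks, got %d: '%s'",
                   length(blocks), id))
    parts <- lapply(blocks, function(b) trimws(strsplit(b, ":", fixed = TRUE)[[1]]))
    if (any(lengths(parts) != 4))
      stop("each exon block must be 'chrom:start:end:strand': '", id, "'")
    chrom <- vapply(parts, `[`, character(1), 1)
    strand <- vapply(parts, `[`, character(1), 4)
    starts <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 2)))
    ends <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 3)))
    if (anyNA(starts) || anyNA(ends))
      stop("non-numeric coordinate in event id: '", id, "'")
    if (length(unique(chrom)) != 1)
      stop("inconsistent chromosome across exon blocks: '", id, "'")
    if (length(unique(strand)) != 1 || !strand[1] %in% c("+", "-"))
      stop("inconsistent or invalid strand across exon blocks: '", id, "'")
    data.frame(chrom = chrom[1], strand = strand[1],
               up_start = starts[1], up_end = ends[1],
               se_start = starts[2], se_end = ends[2],
               dn_start = starts[3], dn_end = ends[3],
               stringsAsFactors = FALSE)
  })
  ev <- do.call(rbind, recs)
  ev$event_id <- serializeEventId(ev)
  SpliceEventCatalog(ev[, .EVENT_COLS])
}

#' Serialize skipped-exon events to canonical MISO-style ids
#'
#' @param events a [SpliceEventCatalog-class] or its event data.frame.
#' @return Character vector of canonical ids (no whitespace).
#' @export
serializeEventId <- function(events) {
  ev <- if (is(events, "SpliceEventCatalog")) events@events else events
  sprintf("%s:%s:%s:%s@%s:%s:%s:%s@%s:%s:%s:%s",
          ev$chrom, format(ev$up_start, scientific = FALSE, trim = TRUE),
          format(ev$up_end, scientific = FALSE, trim = TRUE), ev$strand,
          ev$chrom, format(ev$se_start, scientific = FALSE, trim = TRUE),
          format(ev$se_end, scientific = FALSE, trim = TRUE), ev$strand,
          ev$chrom, format(ev$dn_start, scientific = FALSE, trim = TRUE),
          format(ev$dn_end, scientific = FALSE, trim = TRUE), ev$strand)
}

#' Read a skipped-exon event catalog
#'
#' One MISO-style event id per line.
#'
#' @param path path to a text file of event ids.
#' @return A [SpliceEventCatalog-class].
#' @export
readEventCatalog <- function(path) {
  ids <- readLines(path)
  ids <- ids[nzchar(trimws(ids))]
  parseEventId(ids)
}

#' Write a skipped-exon event catalog
#'
#' @param events a [SpliceEventCatalog-class].
#' @param path output path (one canonical event id per line).
#' @return `path`, invisibly.
#' @export
writeEventCatalog <- function(events, path) {
  writeLines(eventIds(events), path)
  invisible(path)
}

#' Enumerate skipped-exon events from a GTF annotation
#'
#' For every transcript with at least three exons, each internal exon
#' (excluding the first and last) yields one candidate skipped-exon event
#' with its two coordinate-adjacent exons as flanks.  Duplicated events
#' (identical exon triples from different transcripts) are collapsed.
#'
#' @param path path to a GTF/GFF file with exon features carrying a
#'   `transcript_id` attribute.
#' @return A [SpliceEventCatalog-class].
#' @export
eventsFromGtf <- function(path) {
  gr <- rtracklayer::import(path)
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "exon"]
  if (is.null(gr$transcript_id))
    stop("GTF exons must carry a transcript_id attribute")
  recs <- lapply(S4Vectors::split(gr, gr$transcript_id), function(tx) {
    tx <- tx[order(GenomicRanges::start(tx))]
    n <- length(tx)
    if (n < 3) return(NULL)
    idx <- 2:(n - 1)
    data.frame(chrom = as.character(GenomicRanges::seqnames(tx))[idx],
               strand = as.character(GenomicRanges::strand(tx))[idx],
               up_start = GenomicRanges::start(tx)[idx - 1],
               up_end = GenomicRanges::end(tx)[idx - 1],
               se_start = GenomicRanges::start(tx)[idx],
               se_end = GenomicRanges::end(tx)[idx],
               dn_start = GenomicRanges::start(tx)[idx + 1],
               dn_end = GenomicRanges::end(tx)[idx + 1],
               stringsAsFactors = FALSE)
  })
  ev <- do.call(rbind, c(recs, list(make.row.names = FALSE)))
  if (is.null(ev) || !nrow(ev)) {
    ev <- data.frame(event_id = character(), chrom = character(),
                     strand = character(), up_start = numeric(),
                     up_end = numeric(), se_start = numeric(),
                     se_end = numeric(), dn_start = numeric(),
                     dn_end = numeric(), stringsAsFactors = FALSE)
    return(SpliceEventCatalog(ev))
  }
  ev$event_id <- serializeEventId(ev)
  ev <- ev[!duplicated(ev$event_id), .EVENT_COLS]
  SpliceEventCatalog(ev)
}

# ---- eCLIP peaks ------------------------------------------------------------

.emptyPeaks <- function() {
  gr <- GenomicRanges::GRanges()
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    enrichment = numeric(), pvalue = numeric(), rbp = character(),
    cell_line = character(), replicate = integer())
  gr
}

#' Read an eCLIP peak file
#'
#' Reads a narrowPeak (BED6+4: signalValue = fold enrichment, pValue =
#' -log10 p) or plain BED6+2 file (fold enrichment and literal p-value as
#' columns 7-8) into a `GRanges` annotated with `enrichment`, `pvalue`,
#' `rbp`, `cell_line` and `replicate`.  BED coordinates (0-based half-open)
#' are converted to the 1-based closed `GRanges` convention on read; all
#' downstream interval arithmetic uses that one convention.
#'
#' @param path path to the peak file.
#' @param rbp RBP name the file belongs to.
#' @param cell_line cell line label (e.g. "K562", "HepG2").
#' @param replicate replicate number.
#' @param format `"narrowPeak"` (default; pValue column is -log10 p) or
#'   `"bed6p"` (columns 7-8 are enrichment and a literal p-value).
#' @return A `GRanges` of peaks, in file order.
#' @export
readPeaks <- function(path, rbp, cell_line = "", replicate = 1L,
                      format = c("narrowPeak", "bed6p")) {
  format <- match.arg(format)
  if (file.size(path) == 0) return(.emptyPeaks())
  extra <- if (format == "narrowPeak")
    c(signalValue = "numeric", pValue = "numeric", qValue = "numeric",
      peak = "integer")
  else
    c(enrichment = "numeric", pvalue = "numeric")
  gr <- tryCatch(
    rtracklayer::import(path, format = "BED", extraCols = extra),
    error = function(e)
      stop("malformed peak file '", path, "' (expected ",
           if (format == "narrowPeak") "narrowPeak BED6+4" else "BED6+2",
           "): ", conditionMessage(e)))
  if (format == "narrowPeak") {
    gr$enrichment <- gr$signalValue
    gr$pvalue <- 10^(-gr$pValue)
    gr$signalValue <- gr$pValue <- gr$qValue <- gr$peak <- NULL
  }
  if (any(gr$enrichment <= 0))
    stop("peak fold enrichment must be > 0")
  if (any(gr$pvalue <= 0 | gr$pvalue > 1))
    stop("peak p-values must lie in (0, 1]")
  gr$name <- gr$score <- NULL
  gr$rbp <- rbp
  gr$cell_line <- cell_line
  gr$replicate <- as.integer(replicate)
  gr
}

# ---- triplet result tables --------------------------------------------------

.TRIPLET_COLS <- c("modulator", "rbp", "event", "beta0", "beta1", "beta2",
                   "beta3", "p", "q", "pcc_low", "p_low", "n_low",
                   "pcc_high", "p_high", "n_high", "category")

#' Write a triplet result table
#'
#' Writes the fixed-order tab-separated result table (modulator, rbp, event,
#' beta0..beta3, p, q, pcc_low, p_low, n_low, pcc_high, p_high, n_high,
#' category).  Columns absent from `records` are written as NA.
#'
#' @param records data.frame of screened/annotated triplets.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTripletTable <- function(records, path) {
  out <- records
  for (cc in setdiff(.TRIPLET_COLS, names(out))) out[[cc]] <- NA
  out <- out[, .TRIPLET_COLS, drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a triplet result table
#'
#' @param path path written by [writeTripletTable()].
#' @return data.frame in the fixed column order.
#' @export
readTripletTable <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}
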