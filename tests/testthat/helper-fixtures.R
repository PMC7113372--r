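# Shared fixture builders (all data generated in code).

# small valid expression matrix
makeExpr <- function(n_genes = 3, n_samples = 4, seed = 1) {
  set.seed(seed)
  m <- matrix(round(runif(n_genes * n_samples, 0, 100), 3),
              n_genes, n_samples,
              dimnames = list(sprintf("G%02d", seq_len(n_genes)),
                              sprintf("S%02d", seq_len(n_samples))))
  ExpressionMatrix(m)
}

# random valid skipped-exon event records
randomEvents <- function(n, seed = 1) {
  set.seed(seed)
  recs <- lapply(seq_len(n), function(i) {
    a <- sort(sample(1:100000, 6))
    data.frame(chrom = sample(c("chr1", "chr2", "chrX"), 1),
               strand = sample(c("+", "-"), 1),
               up_start = a[1], up_end = a[2], se_start = a[3],
               se_end = a[4], dn_start = a[5], dn_end = a[6],
               stringsAsFactors = FALSE)
  })
  ev <- do.call(rbind, recs)
  ev$event_id <- serializeEventId(ev)
  ev <- ev[!duplicated(ev$event_id), ]
  SpliceEventCatalog(ev[, c("event_id", "chrom", "strand", "up_start",
                            "up_end", "se_start", "se_end", "dn_start",
                            "dn_end")])
}

# build a peak GRanges directly (1-based closed coordinates)
makePeaks <- function(chrom, start, end, rbp, enrichment = 10,
                      pvalue = 1e-6, cell_line = "K562", replicate = 1L,
                      strand = "+") {
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start = start, end = end),
                               strand = strand)
  gr$enrichment <- enrichment
  gr$pvalue <- pvalue
  gr$rbp <- rbp
  gr$cell_line <- cell_line
  gr$replicate <- as.integer(replicate)
  gr
}

# write narrowPeak lines to a temp file
writeNarrowPeak <- function(lines, path = tempfile(fileext = ".narrowPeak")) {
  writeLines(lines, path)
  path
}

# simulate one triplet's raw vectors under the logistic-link model
simTriplet <- function(n = 480, b0 = 0, b1 = 0.5, b3 = 0, noise_sd = 1,
                       missing_rate = 0.1) {
  s_r <- rnorm(n)
  s_m <- rnorm(n)
  psi <- plogis(b0 + (b1 + b3 * s_m) * s_r + rnorm(n, 0, noise_sd))
  if (missing_rate > 0) psi[runif(n) < missing_rate] <- NA
  list(rbp = s_r, mod = s_m, psi = psi)
}
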