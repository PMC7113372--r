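# Peak filtering, replicate union, exon windows and target mapping.

test_that("peak filter applies enrichment (inclusive) and p-value cutoffs", {
  pk <- makePeaks("chr1", c(100, 300, 500, 700), c(200, 400, 600, 800),
                  rbp = "QKI",
                  enrichment = c(10, 7, 12, 8),
                  pvalue = c(1e-6, 1e-9, 1e-4, 1e-6))
  kept <- filterPeaks(pk, mappingConfig())
  expect_equal(GenomicRanges::start(kept), c(100, 700))
  expect_equal(kept$enrichment, c(10, 8))   # = 8 kept (log2FC >= 3 reading)
})

test_that("replicate/cell-line union merges overlapping and book-ended peaks", {
  # BED [100, 200) and [150, 250) -> 1-based [101, 200] and [151, 250]
  pk <- c(makePeaks("chr1", 101, 200, "QKI", replicate = 1),
          makePeaks("chr1", 151, 250, "QKI", replicate = 2,
                    cell_line = "HepG2"),
          makePeaks("chr1", 301, 400, "QKI"),
          makePeaks("chr1", 401, 450, "QKI"))          # book-ended with prev
  merged <- unionReplicates(pk)
  expect_equal(length(merged), 2L)
  expect_equal(GenomicRanges::start(merged), c(101, 301))
  expect_equal(GenomicRanges::end(merged), c(250, 450))
  expect_equal(merged$n_peaks, c(2L, 2L))
  # disjoint intervals from different RBPs are never pooled together
  pk2 <- c(makePeaks("chr1", 101, 200, "A"), makePeaks("chr1", 150, 250, "B"))
  m2 <- unionReplicates(pk2)
  expect_equal(length(m2), 2L)
  expect_setequal(m2$rbp, c("A", "B"))
})

test_that("merged intervals are disjoint, sorted, and no longer than inputs", {
  set.seed(21)
  for (rep_i in 1:10) {
    s <- sample(1:900, 30, replace = TRUE)
    pk <- makePeaks("chr1", s, s + sample(5:80, 30, replace = TRUE), "R1")
    m <- unionReplicates(pk)
    st <- GenomicRanges::start(m); en <- GenomicRanges::end(m)
    expect_true(all(diff(st) > 0))
    if (length(m) > 1)
      expect_true(all(st[-1] > en[-length(en)] + 1))  # disjoint, not adjacent
    expect_lte(sum(GenomicRanges::width(m)), sum(GenomicRanges::width(pk)))
  }
})

test_that("event windows extend the skipped exon symmetrically and clip at 1", {
  ev <- parseEventId(paste0("chr11:57582866:57582972:+@",
                            "chr11:57583387:57583473:+@",
                            "chr11:57583769:57586652:+"))
  w <- eventWindows(ev, mappingConfig(flank_bp = 300))
  expect_equal(GenomicRanges::start(w), 57583087)
  expect_equal(GenomicRanges::end(w), 57583773)
  w0 <- eventWindows(ev, mappingConfig(flank_bp = 0))
  expect_equal(c(GenomicRanges::start(w0), GenomicRanges::end(w0)),
               c(57583387, 57583473))
  near <- SpliceEventCatalog(data.frame(
    event_id = "e", chrom = "chr1", strand = "+", up_start = 10, up_end = 40,
    se_start = 100, se_end = 150, dn_start = 200, dn_end = 250))
  wn <- eventWindows(near, mappingConfig(flank_bp = 300))
  expect_equal(GenomicRanges::start(wn), 1)
})

test_that("target mapping needs >= 1 shared base with the flanked window", {
  ev <- parseEventId(paste0("chr11:57582866:57582972:+@",
                            "chr11:57583387:57583473:+@",
                            "chr11:57583769:57586652:+"))
  # window is [57583087, 57583773]; merged interval [57583001, 57583200]
  hit <- makePeaks("chr11", 57583001, 57583200, "QKI")
  hit$n_peaks <- 1L
  tm <- mapTargets(hit, ev, mappingConfig())
  expect_equal(nrow(targetTable(tm)), 1L)
  expect_equal(targetTable(tm)$rbp, "QKI")
  # interval whose last base is window start - 1: no overlap
  miss <- makePeaks("chr11", 57582900, 57583086, "QKI")
  miss$n_peaks <- 1L
  expect_equal(nrow(targetTable(mapTargets(miss, ev, mappingConfig()))), 0L)
  # off-chromosome peaks produce a warning and no targets
  off <- makePeaks("chr7", 100, 200, "QKI"); off$n_peaks <- 1L
  expect_warning(tm3 <- mapTargets(off, ev, mappingConfig()),
                 "no chromosome shared")
  expect_equal(nrow(targetTable(tm3)), 0L)
})

test_that("mapping agrees with a brute-force per-base oracle", {
  # oracle: an event is a target iff any filtered-peak base falls inside
  # the per-base expansion of its window, computed by set intersection
  set.seed(31)
  for (rep_i in 1:8) {
    n_ev <- 5
    se_start <- sort(sample(seq(50, 900, by = 150), n_ev))
    ev <- data.frame(event_id = sprintf("e%d", 1:n_ev), chrom = "c1",
                     strand = "+", up_start = se_start - 40,
                     up_end = se_start - 30, se_start = se_start,
                     se_end = se_start + 20, dn_start = se_start + 60,
                     dn_end = se_start + 70)
    cat1 <- SpliceEventCatalog(ev)
    s <- sample(1:950, 12, replace = TRUE)
    pk <- makePeaks("c1", s, pmin(s + sample(3:50, 12, replace = TRUE), 1000),
                    rbp = sample(c("R1", "R2"), 12, replace = TRUE))
    cfg <- mappingConfig(flank_bp = 25)
    merged <- unionReplicates(pk)
    got <- targetTable(mapTargets(merged, cat1, cfg))
    got_keys <- paste(got$rbp, got$event_id)
    want_keys <- character()
    for (r in c("R1", "R2")) {
      covered <- unique(unlist(mapply(
        seq, GenomicRanges::start(pk)[pk$rbp == r],
        GenomicRanges::end(pk)[pk$rbp == r], SIMPLIFY = FALSE)))
      for (i in seq_len(n_ev)) {
        win <- seq(max(1, ev$se_start[i] - 25), ev$se_end[i] + 25)
        if (length(intersect(covered, win)))
          want_keys <- c(want_keys, paste(r, ev$event_id[i]))
      }
    }
    expect_setequal(got_keys, want_keys)
  }
})

test_that("a larger flank never removes a target", {
  set.seed(41)
  ev <- randomEvents(10, seed = 41)
  recs <- eventRecords(ev)
  s <- sample(1:100000, 40, replace = TRUE)
  pk <- makePeaks(sample(c("chr1", "chr2", "chrX"), 40, replace = TRUE),
                  s, s + 200, rbp = "R1")
  merged <- unionReplicates(pk)
  keys <- function(flank) {
    tt <- targetTable(mapTargets(merged, ev, mappingConfig(flank_bp = flank)))
    paste(tt$rbp, tt$event_id)
  }
  k0 <- keys(0); k300 <- keys(300); k1000 <- keys(1000)
  expect_true(all(k0 %in% k300))
  expect_true(all(k300 %in% k1000))
})
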