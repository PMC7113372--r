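# Summary tables, pattern matrix, clustering and the pipeline driver.

mkRecords <- function() {
  data.frame(
    modulator = c("M1", "M1", "M2", "M2", "M3", "M3"),
    rbp = "QKI",
    event = c("E1", "E2", "E1", "E2", "E3", "E4"),
    category = c("AEE", "AEI", "EEE", "EEI", "ExonIE", "ExonEI"),
    stringsAsFactors = FALSE)
}

test_that("category counts are exact and conserved", {
  cc <- categoryCounts(mkRecords())
  expect_equal(sum(cc$n), 6L)
  expect_true(all(cc$n == 1L))
  expect_setequal(cc$category, MODULATION_CATEGORIES)
  expect_equal(nrow(categoryCounts(mkRecords()[0, ])), 0L)
  # conservation on a larger random table
  set.seed(8)
  rec <- data.frame(modulator = sample(paste0("M", 1:5), 40, TRUE),
                    rbp = sample(c("R1", "R2"), 40, TRUE),
                    event = paste0("E", 1:40),
                    category = sample(c(MODULATION_CATEGORIES,
                                        "UNCLASSIFIED"), 40, TRUE))
  expect_equal(sum(categoryCounts(rec)$n), 40L)
})

test_that("top modulators rank by distinct events with lexicographic ties", {
  rec <- data.frame(
    modulator = c("A", "A", "A", "B", "B", "B", "C"),
    rbp = "R",
    event = c("E1", "E2", "E1", "E1", "E2", "E3", "E9"),
    category = "AEE", stringsAsFactors = FALSE)
  top <- topModulators(rec, 10)
  expect_equal(top$modulator, c("B", "A", "C"))   # 3 > 2 > 1 distinct events
  expect_equal(top$n_events, c(3L, 2L, 1L))
  # ties broken lexicographically
  rec2 <- rec[rec$modulator != "B", ]
  rec2$modulator[rec2$modulator == "C"] <- "AA"
  rec2 <- rbind(rec2, data.frame(modulator = "AA", rbp = "R", event = "E2",
                                 category = "AEE"))
  top2 <- topModulators(rec2, 1)
  expect_equal(top2$modulator, "A")               # "A" < "AA" at 2 events each
  expect_equal(nrow(topModulators(rec, 99)), 3L)
})

test_that("pattern matrix encodes categories and rejects duplicates", {
  pm <- modulatorPatternMatrix(mkRecords())
  expect_equal(dim(pm), c(3L, 4L))
  expect_equal(pm["M1", "QKI|E1"], 1L)   # AEE
  expect_equal(pm["M1", "QKI|E2"], 2L)   # AEI
  expect_equal(pm["M2", "QKI|E1"], 3L)   # EEE
  expect_equal(pm["M3", "QKI|E3"], 5L)   # ExonIE
  expect_equal(pm["M3", "QKI|E1"], 0L)   # absent
  # density equals records / (rows x cols)
  expect_equal(sum(pm > 0) / length(pm), 6 / 12)
  dup <- rbind(mkRecords(), mkRecords()[1, ])
  expect_error(modulatorPatternMatrix(dup), "duplicate")
  # single record
  pm1 <- modulatorPatternMatrix(mkRecords()[1, ])
  expect_equal(dim(pm1), c(1L, 1L))
  expect_equal(pm1[1, 1], 1L)
})

test_that("clustering splits identical-pattern groups perfectly", {
  pat <- rbind(matrix(rep(c(1L, 1L, 0L, 6L), 4), 4, byrow = TRUE),
               matrix(rep(c(6L, 0L, 3L, 1L), 3), 3, byrow = TRUE))
  rownames(pat) <- paste0("M", 1:7)
  cl <- clusterModulators(pat, 2)
  expect_equal(length(unique(cl[1:4])), 1L)
  expect_equal(length(unique(cl[5:7])), 1L)
  expect_false(cl[1] == cl[5])
  # k = rows gives singletons; bad k errors
  expect_equal(length(unique(clusterModulators(pat, 7))), 7L)
  expect_error(clusterModulators(pat, 0), "k must")
  expect_error(clusterModulators(pat, 8), "k must")
})

test_that("planted two-pattern cohorts are recovered exactly", {
  set.seed(14)
  pat <- matrix(0L, 10, 6)
  pat[1:5, 1:3] <- sample(1:6, 15, TRUE)
  pat[6:10, 4:6] <- sample(1:6, 15, TRUE)
  rownames(pat) <- paste0("M", 1:10)
  cl <- clusterModulators(pat, 2)
  expect_equal(length(unique(cl[1:5])), 1L)
  expect_equal(length(unique(cl[6:10])), 1L)
  expect_false(cl[1] == cl[6])
})

test_that("modulator correlation matrix is a valid Pearson matrix", {
  expr <- makeExpr(4, 30, seed = 44)
  mc <- modulatorCorrelation(expr, c("G01", "G02", "G03"))
  expect_equal(dim(mc), c(3L, 3L))
  expect_equal(unname(diag(mc)), rep(1, 3))
  expect_true(all(abs(mc) <= 1))
  expect_equal(mc, t(mc))
  expect_error(modulatorCorrelation(expr, "NOPE"), "absent")
})

test_that("the pipeline runs end to end on a simulated cohort", {
  out1 <- tempfile()
  config <- list(
    seed = 1,
    simulate = list(n_samples = 200, n_rbps = 3, n_modulators = 8,
                    n_events = 24, fraction_planted = 0.5, seed = 42),
    filters = list(min_samples_above_min_psi = 40, min_non_missing = 40),
    screen = list(fdr = 0.05),
    summaries = list(top_n = 5, k_clusters = 2))
  res <- suppressMessages(runPipeline(config, out1))
  expect_true(file.exists(res$paths$triplets))
  expect_true(file.exists(res$paths$funnel))
  funnel <- res$funnel
  expect_equal(funnel$count[funnel$stage == "events_total"], 24)
  # selected triplets written with categories
  tab <- readTripletTable(res$paths$triplets)
  expect_true(all(tab$category %in% c(MODULATION_CATEGORIES, "UNCLASSIFIED")))
  # planted strong-effect triplets dominate the selections
  truth <- utils::read.delim(file.path(out1, "fixture", "truth.tsv"))
  if (nrow(tab)) {
    planted_keys <- paste(truth$event_id, truth$modulator)
    expect_gt(mean(paste(tab$event, tab$modulator) %in% planted_keys), 0.5)
  }
  # determinism: identical config + seed => identical triplet table
  out2 <- tempfile()
  res2 <- suppressMessages(runPipeline(config, out2))
  expect_identical(readLines(res$paths$triplets),
                   readLines(res2$paths$triplets))
})

test_that("impossible thresholds give empty but valid pipeline outputs", {
  out <- tempfile()
  config <- list(
    seed = 2,
    simulate = list(n_samples = 120, n_rbps = 2, n_modulators = 4,
                    n_events = 6, seed = 9),
    filters = list(min_cv = 10, min_samples_above_min_psi = 10,
                   min_non_missing = 10))
  res <- suppressMessages(runPipeline(config, out))
  expect_equal(nrow(res$triplets), 0L)
  expect_true(file.exists(res$paths$triplets))
  tab <- readTripletTable(res$paths$triplets)
  expect_equal(nrow(tab), 0L)
})
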