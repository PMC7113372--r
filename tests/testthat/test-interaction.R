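# The difference-in-proportions interaction fit, its OLS identity, BH
# adjustment and the triplet screen.

# build label vectors realising given cell proportions exactly
labelsFromCells <- function(p, n_per_cell = 25) {
  t_lab <- unlist(lapply(p, function(pp) {
    k <- round(pp * n_per_cell)
    c(rep(1L, k), rep(0L, n_per_cell - k))
  }))
  list(r = rep(c(0L, 0L, 1L, 1L), each = n_per_cell),
       m = rep(c(0L, 1L, 0L, 1L), each = n_per_cell),
       t = t_lab)
}

test_that("interaction fit reproduces the worked proportions example", {
  lb <- labelsFromCells(c(0.2, 0.2, 0.2, 0.8), 25)  # (00, 01, 10, 11)
  fit <- interactionFit(lb$r, lb$m, lb$t)
  expect_equal(fit$beta0, 0.2)
  expect_equal(fit$beta3, 0.6)
  expect_equal(fit$se3, 0.16)
  expect_equal(fit$z, 3.75)
  expect_equal(fit$p, 2 * pnorm(-3.75))   # ~ 1.77e-4
  expect_equal(fit$n_retained, 100L)
  expect_equal(as.vector(fit$cell_counts), rep(25L, 4))
})

test_that("equal cell proportions give a zero interaction", {
  lb <- labelsFromCells(rep(0.4, 4), 20)
  fit <- interactionFit(lb$r, lb$m, lb$t)
  expect_equal(fit$beta3, 0)
})

test_that("beta3 equals the OLS interaction coefficient on the 0/1 design", {
  set.seed(12)
  for (i in 1:200) {
    n <- sample(60:480, 1)
    d <- lapply(1:3, function(j) tertileDiscretize(rnorm(n)))
    mask <- retainedMask(d[[1]], d[[2]], d[[3]])
    fit <- tryCatch(interactionFit(d[[1]], d[[2]], d[[3]], mask,
                                   min_cell_count = 1L),
                    error = function(e) NULL)
    if (is.null(fit)) next
    ols <- lm(d[[3]][mask] ~ d[[1]][mask] * d[[2]][mask])
    expect_equal(fit$beta3, unname(coef(ols)[4]), tolerance = 1e-10)
    expect_equal(fit$beta0, unname(coef(ols)[1]), tolerance = 1e-10)
  }
})

test_that("fit is invariant under joint relabeling and antisymmetric in the target", {
  set.seed(13)
  d1 <- tertileDiscretize(rnorm(200))
  d2 <- tertileDiscretize(rnorm(200))
  d3 <- tertileDiscretize(rnorm(200))
  f <- interactionFit(d1, d2, d3)
  # flip both rbp and modulator labels: beta3 unchanged
  f_flip <- interactionFit(1L - d1, 1L - d2, d3)
  expect_equal(f_flip$beta3, f$beta3)
  expect_equal(f_flip$p, f$p)
  # flip target labels: beta3 negated
  f_neg <- interactionFit(d1, d2, 1L - d3)
  expect_equal(f_neg$beta3, -f$beta3)
})

test_that("undersized design cells abort with a classed error", {
  lb <- labelsFromCells(rep(0.5, 4), 4)
  expect_error(interactionFit(lb$r, lb$m, lb$t, min_cell_count = 5L),
               class = "spliceMod_undersized_cell")
})

test_that("BH adjustment matches the step-up formula", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(0.2), 0.2)
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  expect_equal(bhAdjust(c(0.001, 0.5)), c(0.002, 0.5))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("a planted strong interaction is recovered among nulls", {
  cfg <- simConfig(n_samples = 480, n_rbps = 4, n_modulators = 1,
                   n_events = 100, fraction_planted = 0.01,
                   plant_effects = "fixed", b3 = 0.5, seed = 101)
  co <- simulateCohort(cfg)
  tr <- cohortTruth(co)
  planted <- tr[tr$planted, ]
  expect_equal(nrow(planted), 1L)
  res <- screenTriplets(cohortExpr(co), cohortPsi(co), cohortTargets(co),
                        "MOD0001")
  expect_true(paste(planted$event_id, planted$modulator) %in%
                paste(res$event, res$modulator))
  # selected rows are sorted by q then |beta3|
  if (nrow(res) > 1) expect_true(!is.unsorted(res$q))
})

test_that("all-null screens rarely select anything at fdr 0.01", {
  cfg <- simConfig(n_samples = 480, n_rbps = 5, n_modulators = 1,
                   n_events = 500, fraction_planted = 0, seed = 77)
  co <- simulateCohort(cfg)
  res <- screenTriplets(cohortExpr(co), cohortPsi(co), cohortTargets(co),
                        "MOD0001")
  expect_lte(nrow(res), 5L)
})

test_that("screen output is monotone in the FDR threshold and empty maps work", {
  cfg <- simConfig(n_samples = 240, n_rbps = 2, n_modulators = 4,
                   n_events = 30, fraction_planted = 0.5, seed = 55)
  co <- simulateCohort(cfg)
  mods <- sprintf("MOD%04d", 1:4)
  strict <- screenTriplets(cohortExpr(co), cohortPsi(co), cohortTargets(co),
                           mods, screenConfig(fdr = 0.001))
  loose <- screenTriplets(cohortExpr(co), cohortPsi(co), cohortTargets(co),
                          mods, screenConfig(fdr = 0.05))
  key <- function(x) paste(x$modulator, x$rbp, x$event)
  expect_true(all(key(strict) %in% key(loose)))
  # empty target map
  empty_map <- RbpTargetMap(data.frame(rbp = character(),
                                       event_id = character(),
                                       n_support = integer()))
  out <- screenTriplets(cohortExpr(co), cohortPsi(co), empty_map, mods)
  expect_equal(nrow(out), 0L)
  # the funnel accounts for every enumerated triplet
  all_rows <- screenTriplets(cohortExpr(co), cohortPsi(co),
                             cohortTargets(co), mods, all = TRUE)
  fn <- attr(all_rows, "funnel")
  expect_equal(unname(fn["tested"] + fn["skipped"]), 30L * 4L)
})

test_that("the continuous OLS estimator flags the same planted triplet", {
  cfg <- simConfig(n_samples = 480, n_rbps = 2, n_modulators = 1,
                   n_events = 40, fraction_planted = 0.025,
                   plant_effects = "fixed", b3 = 0.6, seed = 202)
  co <- simulateCohort(cfg)
  tr <- cohortTruth(co)
  res <- screenTriplets(cohortExpr(co), cohortPsi(co), cohortTargets(co),
                        "MOD0001",
                        screenConfig(estimator = "continuous-ols"))
  expect_true(tr$event_id[tr$planted] %in% res$event)
})
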