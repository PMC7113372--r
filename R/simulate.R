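# Synthetic cohort generator: CPM-like log-normal expression, PSI through a
# logistic link with planted modulator interactions, uniform missingness,
# and fixture emission (TSV matrices, MISO-style event ids on a synthetic
# chromosome, narrowPeak files reproducing the truth target map).

# expected |standardized modulator expression| within the bottom/top third
# of a normal: E[Z | Z > q_{2/3}] = 3 * dnorm(qnorm(2/3))
.tertileDelta <- function() 3 * stats::dnorm(stats::qnorm(2 / 3))

# deterministic genomic layout of simulated events on chromosome "chrS":
# per event a 3 kb tile holding the three exons, so that +/-300 bp windows
# of different events never touch
.SIM_TILE <- 3000L
.simEventTable <- function(n_events) {
  base <- (seq_len(n_events) - 1L) * .SIM_TILE
  ev <- data.frame(chrom = "chrS", strand = "+",
                   up_start = base + 1, up_end = base + 100,
                   se_start = base + 401, se_end = base + 500,
                   dn_start = base + 801, dn_end = base + 900,
                   stringsAsFactors = FALSE)
  ev$event_id <- serializeEventId(ev)
  ev[, .EVENT_COLS]
}

#' Effect sizes that realise one modulation category
#'
#' Returns logistic-link parameters `(b0, b1, b3)` whose implied RBP slopes
#' in the modulator-low and modulator-high thirds match the category's
#' semantics.  With `delta = E[|s_m|]` within an extreme tertile of a
#' normal modulator, the group slopes are `b1 -/+ b3 * delta`; the
#' magnitudes (strong 1.8 / weak 0.6, inversions +/-1.2) are chosen so both
#' group correlations clear the detection threshold at the default cohort
#' size.
#'
#' @param category one of `MODULATION_CATEGORIES`.
#' @param cfg a [SimConfig-class] (reserved for scaling; the defaults use
#'   fixed strong effects).
#' @return Named numeric vector `c(b0, b1, b3)`.
#' @export
plantCategory <- function(category, cfg = simConfig()) {
  slopes <- switch(category,
                   AEE = c(-1.8, -0.6),     # both exon-exclusion, fading
                   EEE = c(-0.6, -1.8),     # both exon-exclusion, growing
                   AEI = c(1.8, 0.6),       # both exon-inclusion, fading
                   EEI = c(0.6, 1.8),       # both exon-inclusion, growing
                   ExonIE = c(1.2, -1.2),   # inclusion flips to exclusion
                   ExonEI = c(-1.2, 1.2),   # exclusion flips to inclusion
                   stop("unknown modulation category: ", category))
  delta <- .tertileDelta()
  c(b0 = 0,
    b1 = (slopes[1] + slopes[2]) / 2,
    b3 = (slopes[2] - slopes[1]) / (2 * delta))
}

#' Simulate a triplet cohort
#'
#' Draws CPM-like log-normal expression for `n_rbps + n_modulators` genes,
#' assigns each of `n_events` skipped-exon events to an RBP (round-robin)
#' and generates its PSI through a logistic link on the standardized
#' log-expression `s_r` of that RBP:
#' `PSI = plogis(b0 + (b1 + b3 * s_m) * s_r + eps)`, with
#' `eps ~ Normal(0, noise_sd)`.  A planted event has one modulator `m` with
#' `b3 != 0` (from [plantCategory()] or the fixed `b0/b1/b3` of the
#' config); null events have `b3 = 0` and no modulator.  PSI entries are
#' then set missing uniformly at random at `missing_rate`.  The whole
#' cohort is reproducible from `cfg@seed`.
#'
#' @param cfg a [SimConfig-class].
#' @return A [TripletCohort-class] whose truth table has one row per event:
#'   `event_id`, `rbp`, `planted`, `modulator`, `category`, `b0`, `b1`,
#'   `b3`.
#' @export
simulateCohort <- function(cfg = simConfig()) {
  validObject(cfg)
  set.seed(cfg@seed)
  n <- cfg@n_samples
  samples <- sprintf("S%04d", seq_len(n))
  rbp_ids <- sprintf("RBP%03d", seq_len(cfg@n_rbps))
  mod_ids <- sprintf("MOD%04d", seq_len(cfg@n_modulators))
  genes <- c(rbp_ids, mod_ids)

  mu <- stats::runif(length(genes), 4, 8)       # per-gene mean log2 CPM
  cpm <- t(vapply(mu, function(m) 2^stats::rnorm(n, m, 1), numeric(n)))
  dimnames(cpm) <- list(genes, samples)
  expr <- ExpressionMatrix(cpm)
  s <- t(scale(t(log2(cpm + 1))))               # standardized log-expression

  ev <- .simEventTable(cfg@n_events)
  events <- SpliceEventCatalog(ev)
  ev_rbp <- rbp_ids[((seq_len(cfg@n_events) - 1L) %% cfg@n_rbps) + 1L]

  n_planted <- round(cfg@fraction_planted * cfg@n_events)
  if (n_planted > 0 && cfg@n_modulators < 1)
    stop("cannot plant triplets without modulator candidates")
  planted <- rep(FALSE, cfg@n_events)
  planted[sample(cfg@n_events, n_planted)] <- TRUE

  truth <- data.frame(event_id = ev$event_id, rbp = ev_rbp,
                      planted = planted, modulator = NA_character_,
                      category = NA_character_, b0 = cfg@b0, b1 = cfg@b1,
                      b3 = 0, stringsAsFactors = FALSE)
  if (n_planted > 0) {
    idx <- which(planted)
    truth$modulator[idx] <- sample(mod_ids, n_planted, replace = TRUE)
    if (cfg@plant_effects == "category") {
      cats <- sample(names(cfg@category_mix), n_planted, replace = TRUE,
                     prob = cfg@category_mix)
      truth$category[idx] <- cats
      eff <- vapply(cats, plantCategory, numeric(3), cfg = cfg)
      truth$b0[idx] <- eff["b0", ]
      truth$b1[idx] <- eff["b1", ]
      truth$b3[idx] <- eff["b3", ]
    } else {
      truth$b3[idx] <- cfg@b3
    }
  }

  psi_values <- matrix(NA_real_, cfg@n_events, n,
                       dimnames = list(ev$event_id, samples))
  for (i in seq_len(cfg@n_events)) {
    s_r <- s[truth$rbp[i], ]
    slope <- truth$b1[i]
    if (truth$planted[i])
      slope <- slope + truth$b3[i] * s[truth$modulator[i], ]
    eta <- truth$b0[i] + slope * s_r + stats::rnorm(n, 0, cfg@noise_sd)
    psi_values[i, ] <- stats::plogis(eta)
  }
  if (cfg@missing_rate > 0)
    psi_values[stats::runif(length(psi_values)) < cfg@missing_rate] <- NA_real_
  psi <- PsiMatrix(psi_values)

  tgt <- data.frame(rbp = ev_rbp, event_id = ev$event_id, n_support = 1L,
                    stringsAsFactors = FALSE)
  tgt <- tgt[order(tgt$rbp, tgt$event_id), , drop = FALSE]  # mapTargets order
  targets <- RbpTargetMap(tgt, events)
  new("TripletCohort", expr = expr, psi = psi, events = events,
      targets = targets, truth = truth)
}

#' Convert a proportion-scale interaction effect to the logit scale
#'
#' The interaction screen measures the effect as a
#' difference-in-differences (DiD) of upper-tertile inclusion proportions
#' over the four (rbp, modulator) label cells, while the generator plants
#' effects on the logit scale.  This function inverts that relationship: it
#' finds the logit interaction slope `b3` whose implied DiD equals `did`,
#' by root-finding on a large common-random-numbers Monte-Carlo evaluation
#' (deterministic given `mc_seed`; the caller's RNG state is untouched).
#'
#' @param did target difference-in-differences of inclusion proportions.
#' @param b0,b1,noise_sd the other generator parameters.
#' @param n_mc Monte-Carlo sample size of the evaluation.
#' @param mc_seed internal seed of the evaluation draw.
#' @return The logit-scale interaction slope `b3`.
#' @export
didToLogitInteraction <- function(did, b0 = 0, b1 = 0.5, noise_sd = 1,
                                  n_mc = 200000L, mc_seed = 20240301L) {
  if (did == 0) return(0)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(mc_seed)
  s_r <- stats::rnorm(n_mc); s_m <- stats::rnorm(n_mc)
  eps <- stats::rnorm(n_mc, 0, noise_sd)
  lab <- function(x) {
    q <- stats::quantile(x, c(1/3, 2/3), names = FALSE)
    ifelse(x <= q[1], 0L, ifelse(x > q[2], 1L, NA_integer_))
  }
  r_lab <- lab(s_r); m_lab <- lab(s_m)
  implied <- function(b3) {
    eta <- b0 + (b1 + b3 * s_m) * s_r + eps
    t_lab <- lab(eta)                  # plogis is monotone: same tertiles
    ok <- !is.na(r_lab) & !is.na(m_lab) & !is.na(t_lab)
    p <- vapply(list(c(0, 0), c(0, 1), c(1, 0), c(1, 1)), function(cell) {
      sel <- ok & r_lab == cell[1] & m_lab == cell[2]
      mean(t_lab[sel] == 1L)
    }, numeric(1))
    p[4] - p[3] - p[2] + p[1]
  }
  sgn <- sign(did)
  root <- stats::uniroot(function(b3) implied(b3) - abs(did),
                         lower = 0, upper = 20, tol = 1e-4)$root
  sgn * root
}

#' Write a simulated cohort as analysis-ready fixture files
#'
#' Emits, under `dir`: `expression.tsv` and `psi.tsv` (tab-separated
#' matrices; missing PSI written as `"NA"`), `events.txt` (canonical
#' MISO-style ids on the synthetic chromosome), `truth.tsv`, and a `peaks/`
#' directory with two replicate narrowPeak files per RBP whose
#' filtered/merged peaks reproduce the truth target map exactly: each
#' (rbp, event) assignment gets two overlapping replicate peaks inside the
#' skipped exon that pass the default enrichment/p-value cutoffs, plus
#' decoy peaks that fail the enrichment filter and a high-enrichment peak
#' in a window-free desert region.
#'
#' @param cohort a [TripletCohort-class] from [simulateCohort()].
#' @param dir output directory (created if needed).
#' @return Named list of the written paths, invisibly.
#' @export
emitFixtureFiles <- function(cohort, dir) {
  dir.create(file.path(dir, "peaks"), recursive = TRUE, showWarnings = FALSE)
  paths <- list(expression = file.path(dir, "expression.tsv"),
                psi = file.path(dir, "psi.tsv"),
                events = file.path(dir, "events.txt"),
                truth = file.path(dir, "truth.tsv"))
  writeExpressionMatrix(cohortExpr(cohort), paths$expression)
  writePsiMatrix(cohortPsi(cohort), paths$psi)
  writeEventCatalog(cohortEvents(cohort), paths$events)
  utils::write.table(cohortTruth(cohort), paths$truth, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  ev <- eventRecords(cohortEvents(cohort))
  map <- targetTable(cohortTargets(cohort))
  map <- merge(map, ev[c("event_id", "chrom", "se_start", "se_end")],
               by = "event_id", sort = FALSE)
  np_line <- function(chrom, start0, end0, enrich, mlog10p) {
    sprintf("%s\t%d\t%d\t.\t0\t+\t%g\t%g\t-1\t-1",
            chrom, as.integer(start0), as.integer(end0), enrich, mlog10p)
  }
  desert0 <- max(ev$dn_end) + 5000     # beyond every window
  peak_files <- character()
  for (r in sort(unique(map$rbp))) {
    mr <- map[map$rbp == r, , drop = FALSE]
    for (rep_i in 1:2) {
      # replicate peaks jittered but overlapping, inside the skipped exon
      start0 <- mr$se_start - 1L + 10L * rep_i
      lines <- np_line(mr$chrom, start0, start0 + 50L, 10, 8)
      # decoy failing the enrichment cutoff, inside the first window
      lines <- c(lines, np_line(mr$chrom[1], mr$se_start[1] - 1L, mr$se_end[1],
                                2, 8))
      # strong peak overlapping no window at all
      lines <- c(lines, np_line("chrS", desert0, desert0 + 100L, 10, 8))
      f <- file.path(dir, "peaks", sprintf("%s_K562_rep%d.narrowPeak", r, rep_i))
      writeLines(lines, f)
      peak_files <- c(peak_files, f)
    }
  }
  paths$peaks <- peak_files
  invisible(paths)
}

#' Read the peak files emitted by [emitFixtureFiles()]
#'
#' @param dir the fixture directory (narrowPeak files named
#'   `<rbp>_<cell>_rep<k>.narrowPeak`, either directly in `dir` or under
#'   `dir/peaks`).
#' @return A concatenated peak `GRanges` with `rbp`, `cell_line` and
#'   `replicate` parsed from the file names.
#' @export
readFixturePeaks <- function(dir) {
  files <- list.files(dir, pattern = "\\.narrowPeak$", full.names = TRUE)
  if (!length(files))
    files <- list.files(file.path(dir, "peaks"), pattern = "\\.narrowPeak$",
                        full.names = TRUE)
  if (!length(files)) stop("no narrowPeak files under ", dir)
  parts <- regmatches(basename(files),
                      regexec("^(.*)_([^_]+)_rep(\\d+)\\.narrowPeak$",
                              basename(files)))
  grs <- lapply(seq_along(files), function(i) {
    readPeaks(files[i], rbp = parts[[i]][2], cell_line = parts[[i]][3],
              replicate = as.integer(parts[[i]][4]))
  })
  do.call(c, grs)
}
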