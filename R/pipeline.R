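# End-to-end orchestration: filters -> target map -> interaction screen ->
# category classification -> summaries, driven by one YAML configuration.

.cfgSection <- function(config, name) {
  sec <- config[[name]]
  if (is.null(sec)) list() else sec
}

.buildConfig <- function(constructor, args) {
  do.call(constructor, args)
}

#' Run the full triplet pipeline
#'
#' Executes, in order: input loading (or cohort simulation), gene and
#' event eligibility filters, peak filtering/merging and target mapping,
#' the RBP/modulator independence screen, the tertile interaction screen
#' with BH selection, category classification, and summary generation.
#' Every stage count is recorded in a funnel table; all outputs are
#' tab-separated files under `out_dir`.
#'
#' The configuration is a YAML file (or an equivalent named list) with
#' sections `simulate` (arguments of [simConfig()]) *or* `input`
#' (`expression`, `psi`, `events`, `peaks_dir` paths), and optional
#' sections `filters` ([filterConfig()] arguments), `mapping`
#' ([mappingConfig()]), `screen` ([screenConfig()]), `classify` (`alpha`,
#' `frac`), `summaries` (`top_n`, `k_clusters`), `rbps` and `modulators`
#' (explicit gene id lists), and `seed`.
#'
#' @param config path to a YAML configuration file, or a named list.
#' @param out_dir output directory (created if needed); defaults to the
#'   config's `output` entry.
#' @return Invisibly, a list with `triplets` (annotated data.frame),
#'   `funnel` (data.frame of stage counts), and `paths` (written files).
#' @export
runPipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(out_dir)) out_dir <- config$output
  if (is.null(out_dir)) stop("stage config: no output directory given")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)

  fcfg <- .buildConfig(filterConfig, .cfgSection(config, "filters"))
  mcfg <- .buildConfig(mappingConfig, .cfgSection(config, "mapping"))
  scfg <- .buildConfig(screenConfig, .cfgSection(config, "screen"))
  ccfg <- .cfgSection(config, "classify")
  alpha <- if (is.null(ccfg$alpha)) 0.05 else ccfg$alpha
  frac <- if (is.null(ccfg$frac)) 1 / 3 else ccfg$frac
  sumcfg <- .cfgSection(config, "summaries")
  top_n <- if (is.null(sumcfg$top_n)) 10L else sumcfg$top_n
  k_clusters <- sumcfg$k_clusters

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
  }
  funnel <- list()
  note <- function(stage, count) funnel[[length(funnel) + 1]] <<-
    data.frame(stage = stage, count = count, stringsAsFactors = FALSE)

  # ---- inputs ---------------------------------------------------------------
  if (!is.null(config$simulate)) {
    cohort <- stage("simulate",
                    simulateCohort(.buildConfig(simConfig,
                                                config$simulate)))
    fixture_dir <- file.path(out_dir, "fixture")
    stage("simulate", emitFixtureFiles(cohort, fixture_dir))
    input <- list(expression = file.path(fixture_dir, "expression.tsv"),
                  psi = file.path(fixture_dir, "psi.tsv"),
                  events = file.path(fixture_dir, "events.txt"),
                  peaks_dir = fixture_dir)
  } else {
    input <- config$input
    if (is.null(input)) stop("stage input: need a 'simulate' or 'input' section")
  }
  expr <- stage("input", readExpressionMatrix(input$expression))
  psi <- stage("input", readPsiMatrix(input$psi))
  events <- stage("input", readEventCatalog(input$events))
  peaks <- stage("input", readFixturePeaks(input$peaks_dir))
  note("genes_total", nrow(expr)); note("events_total", nrow(psi))
  note("peaks_raw", length(peaks))

  # ---- eligibility filters --------------------------------------------------
  genes_kept <- stage("filter_genes",
                      suppressWarnings(filterGenesByExpression(expr, fcfg)))
  events_kept <- stage("filter_events", filterEvents(psi, fcfg))
  note("genes_kept", length(genes_kept))
  note("events_kept", length(events_kept))

  # ---- target map -----------------------------------------------------------
  peaks_kept <- stage("map_targets", filterPeaks(peaks, mcfg))
  note("peaks_kept", length(peaks_kept))
  merged <- if (length(peaks_kept))
    stage("map_targets",
          unionReplicates(peaks_kept, ignore_strand = !mcfg@strand_specific))
  else .emptyPeaks()
  note("merged_intervals", length(merged))
  tmap <- stage("map_targets", mapTargets(merged, events, mcfg))
  # restrict to events passing filters and present in the PSI matrix
  keep <- targetTable(tmap)$event_id %in% intersect(events_kept, rownames(psi))
  tmap <- RbpTargetMap(targetTable(tmap)[keep, , drop = FALSE])
  note("target_assignments", nrow(targetTable(tmap)))

  # ---- candidate pairs ------------------------------------------------------
  rbp_ids <- if (!is.null(config$rbps)) unlist(config$rbps) else
    intersect(rbps(tmap), geneIds(expr))
  rbp_ids <- intersect(rbp_ids, genes_kept)
  mod_ids <- if (!is.null(config$modulators)) unlist(config$modulators) else
    setdiff(genes_kept, rbp_ids)
  pairs <- if (length(rbp_ids) && length(mod_ids))
    stage("independence", independentPairs(expr, rbp_ids, mod_ids, fcfg))
  else data.frame(rbp = character(), modulator = character(),
                  pcc = numeric(), stringsAsFactors = FALSE)
  note("candidate_pairs", nrow(pairs))

  # ---- interaction screen ---------------------------------------------------
  screened <- stage("screen", screenTriplets(expr, psi, tmap, pairs, scfg))
  sf <- attr(screened, "funnel")
  note("tested_triplets", sf[["tested"]])
  note("skipped_triplets", sf[["skipped"]])
  note("selected_triplets", sf[["selected"]])

  # ---- classification -------------------------------------------------------
  annotated <- stage("classify",
                     annotateTriplets(screened, expr, psi, alpha = alpha,
                                      frac = frac))
  note("classified", sum(annotated$category != "UNCLASSIFIED"))

  # ---- summaries and outputs ------------------------------------------------
  paths <- list(triplets = file.path(out_dir, "triplets.tsv"),
                funnel = file.path(out_dir, "funnel.tsv"),
                category_counts = file.path(out_dir, "category_counts.tsv"),
                top_modulators = file.path(out_dir, "top_modulators.tsv"),
                pattern_matrix = file.path(out_dir, "pattern_matrix.tsv"),
                modulator_correlation = file.path(out_dir,
                                                  "modulator_correlation.tsv"))
  writeTripletTable(annotated, paths$triplets)
  wt <- function(x, p) utils::write.table(x, p, sep = "\t", quote = FALSE,
                                          row.names = FALSE)
  wt(categoryCounts(annotated), paths$category_counts)
  wt(topModulators(annotated, top_n), paths$top_modulators)
  pm <- stage("summarize", modulatorPatternMatrix(annotated))
  utils::write.table(data.frame(modulator = rownames(pm), pm,
                                check.names = FALSE),
                     paths$pattern_matrix, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  used_mods <- sort(unique(annotated$modulator))
  if (length(used_mods) >= 2) {
    mc <- modulatorCorrelation(expr, used_mods)
    utils::write.table(data.frame(modulator = rownames(mc), mc,
                                  check.names = FALSE),
                       paths$modulator_correlation, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  clusters <- NULL
  if (!is.null(k_clusters) && nrow(pm) >= k_clusters && nrow(pm) > 0) {
    clusters <- stage("summarize", clusterModulators(pm, k_clusters))
    paths$clusters <- file.path(out_dir, "clusters.tsv")
    wt(data.frame(modulator = names(clusters), cluster = unname(clusters)),
       paths$clusters)
  }
  funnel_df <- do.call(rbind, funnel)
  wt(funnel_df, paths$funnel)
  message(paste(sprintf("%s: %d", funnel_df$stage, funnel_df$count),
                collapse = "; "))
  invisible(list(triplets = annotated, funnel = funnel_df, paths = paths,
                 clusters = clusters))
}
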