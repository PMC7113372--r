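#' @import methods
#' @importFrom stats cor cor.test dist hclust cutree dnorm pnorm qnorm
#'   p.adjust rnorm runif plogis qlogis sd uniroot lm coef
#' @importFrom utils read.delim write.table head
NULL

# ---- core matrix containers -------------------------------------------------

#' Gene expression matrix (CPM)
#'
#' A numeric matrix of library-size-normalised expression values (counts per
#' million) with genes in rows and samples in columns.  Values must be
#' non-negative and complete; row and column names are the gene and sample
#' identifiers and must be unique.
#'
#' @slot .Data numeric matrix of CPM values.
#' @seealso [readExpressionMatrix()], [PsiMatrix-class]
#' @export
setClass("ExpressionMatrix", contains = "matrix")

setValidity("ExpressionMatrix", function(object) {
  msg <- character()
  if (!is.numeric(object@.Data))
    msg <- c(msg, "expression values must be numeric")
  if (anyNA(object@.Data))
    msg <- c(msg, "expression values must not contain missing entries")
  else if (any(object@.Data < 0))
    msg <- c(msg, "expression values must be non-negative (CPM)")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "gene ids (rownames) must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids (colnames) must be present and unique")
  if (ncol(object) < 2)
    msg <- c(msg, "at least 2 samples are required")
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix, genes x samples, with dimnames.
#' @return An [ExpressionMatrix-class] object.
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' ExpressionMatrix(m)
#' @export
ExpressionMatrix <- function(values) {
  new("ExpressionMatrix", as.matrix(values))
}

#' Percent-spliced-in (PSI) matrix
#'
#' A numeric matrix of exon inclusion levels in `[0, 1]`, events in rows and
#' samples in columns.  `NA` marks a missing PSI estimate for that
#' event/sample.  Sample ids are expected to align by name with a companion
#' [ExpressionMatrix-class].
#'
#' @slot .Data numeric matrix of PSI values with `NA` for missing.
#' @seealso [readPsiMatrix()]
#' @export
setClass("PsiMatrix", contains = "matrix")

setValidity("PsiMatrix", function(object) {
  msg <- character()
  v <- object@.Data
  if (!is.numeric(v))
    msg <- c(msg, "PSI values must be numeric")
  else if (any(v < 0 | v > 1, na.rm = TRUE))
    msg <- c(msg, "PSI values must lie in [0, 1]")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "event ids (rownames) must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids (colnames) must be present and unique")
  if (length(msg)) msg else TRUE
})

#' Construct a PsiMatrix
#'
#' @param values numeric matrix, events x samples, entries in `[0, 1]` or `NA`.
#' @return A [PsiMatrix-class] object.
#' @export
PsiMatrix <- function(values) {
  new("PsiMatrix", as.matrix(values))
}

# ---- splice event catalog ---------------------------------------------------

.EVENT_COLS <- c("event_id", "chrom", "strand",
                 "up_start", "up_end", "se_start", "se_end",
                 "dn_start", "dn_end")

#' Catalog of skipped-exon events
#'
#' Each record describes one skipped-exon (SE) alternative-splicing event as
#' an exon triple on one chromosome and strand: upstream flanking exon,
#' skipped (alternative) exon, downstream flanking exon.  Coordinates are
#' 1-based inclusive and the three exons are non-overlapping and ascending in
#' genomic position, matching the orientation of the MISO-style event id
#' string regardless of strand.
#'
#' @slot events data.frame with columns `event_id`, `chrom`, `strand`,
#'   `up_start`, `up_end`, `se_start`, `se_end`, `dn_start`, `dn_end`.
#' @seealso [parseEventId()], [eventWindows()]
#' @export
setClass("SpliceEventCatalog", representation(events = "data.frame"))

setValidity("SpliceEventCatalog", function(object) {
  ev <- object@events
  msg <- character()
  if (!all(.EVENT_COLS %in% names(ev)))
    return(paste("events must have columns:", paste(.EVENT_COLS, collapse = ", ")))
  if (anyDuplicated(ev$event_id))
    msg <- c(msg, "event ids must be unique")
  if (nrow(ev)) {
    if (!all(ev$strand %in% c("+", "-")))
      msg <- c(msg, "strand must be '+' or '-'")
    bad_exon <- ev$up_start > ev$up_end | ev$se_start > ev$se_end |
      ev$dn_start > ev$dn_end
    if (any(bad_exon))
      msg <- c(msg, "each exon must satisfy start <= end")
    bad_order <- ev$up_end >= ev$se_start | ev$se_end >= ev$dn_start
    if (any(!bad_exon & bad_order))
      msg <- c(msg, "exons must be non-overlapping and coordinate-ascending")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SpliceEventCatalog
#'
#' @param events data.frame of event records (see
#'   [SpliceEventCatalog-class]).
#' @return A [SpliceEventCatalog-class] object.
#' @export
SpliceEventCatalog <- function(events) {
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  rownames(events) <- NULL
  new("SpliceEventCatalog", events = events)
}

# ---- RBP target map ---------------------------------------------------------

#' RBP to splicing-event target map
#'
#' Records which skipped-exon events carry binding evidence for which RBP:
#' one row per (rbp, event) with the number of merged peak intervals
#' supporting the assignment.
#'
#' @slot map data.frame with columns `rbp`, `event_id`, `n_support`.
#' @seealso [mapTargets()]
#' @export
setClass("RbpTargetMap", representation(map = "data.frame"))

setValidity("RbpTargetMap", function(object) {
  m <- object@map
  if (!all(c("rbp", "event_id", "n_support") %in% names(m)))
    return("map must have columns rbp, event_id, n_support")
  msg <- character()
  if (nrow(m)) {
    if (any(m$n_support < 1))
      msg <- c(msg, "supporting interval count must be >= 1")
    if (anyDuplicated(m[c("rbp", "event_id")]))
      msg <- c(msg, "(rbp, event_id) pairs must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an RbpTargetMap
#'
#' @param map data.frame with columns `rbp`, `event_id`, `n_support`.
#' @param events optional [SpliceEventCatalog-class]; when supplied every
#'   `event_id` must exist in the catalog.
#' @return An [RbpTargetMap-class] object.
#' @export
RbpTargetMap <- function(map, events = NULL) {
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  rownames(map) <- NULL
  if (!is.null(events)) {
    missing <- setdiff(map$event_id, eventIds(events))
    if (length(missing))
      stop("event ids absent from the catalog: ",
           paste(head(missing, 5), collapse = ", "))
  }
  new("RbpTargetMap", map = map)
}

# ---- simulated cohort bundle ------------------------------------------------

#' A cohort bundle for triplet analysis
#'
#' Bundles the aligned inputs of one analysis: expression, PSI, the event
#' catalog and the RBP target map, plus (for simulated cohorts) the planted
#' ground truth, one row per event (`event_id`, `rbp`, `planted`,
#' `modulator`, `category`, `b0`, `b1`, `b3`).
#'
#' @slot expr [ExpressionMatrix-class]
#' @slot psi [PsiMatrix-class]
#' @slot events [SpliceEventCatalog-class]
#' @slot targets [RbpTargetMap-class]
#' @slot truth data.frame of planted parameters (zero rows for real cohorts)
#' @seealso [simulateCohort()]
#' @export
setClass("TripletCohort",
         representation(expr = "ExpressionMatrix",
                        psi = "PsiMatrix",
                        events = "SpliceEventCatalog",
                        targets = "RbpTargetMap",
                        truth = "data.frame"))

setValidity("TripletCohort", function(object) {
  msg <- character()
  if (!identical(colnames(object@expr), colnames(object@psi)))
    msg <- c(msg, "expression and PSI sample ids must align 1:1 by name")
  if (!all(rownames(object@psi) %in% eventIds(object@events)))
    msg <- c(msg, "every PSI row must be a cataloged event")
  if (length(msg)) msg else TRUE
})

# ---- configuration objects --------------------------------------------------

#' Gene/event eligibility filter settings
#'
#' @slot min_log2_cpm genes kept when mean `log2(CPM + 1)` reaches this value.
#' @slot min_psi PSI threshold of the prevalence criterion.
#' @slot min_samples_above_min_psi events need PSI above `min_psi` in at
#'   least this many samples.
#' @slot min_non_missing minimum number of non-missing PSI values per event.
#' @slot min_cv events kept when the PSI coefficient of variation exceeds
#'   this value.
#' @slot max_abs_pcc_independence RBP/modulator pairs kept when the absolute
#'   Pearson correlation of their log-expression is at most this value.
#' @slot independence_method `"pcc"` (correlation cap) or `"pvalue"`.
#' @slot independence_alpha p-value cutoff of the `"pvalue"` variant: pairs
#'   kept when the correlation test p-value exceeds it.
#' @export
setClass("FilterConfig",
         representation(min_log2_cpm = "numeric",
                        min_psi = "numeric",
                        min_samples_above_min_psi = "integer",
                        min_non_missing = "integer",
                        min_cv = "numeric",
                        max_abs_pcc_independence = "numeric",
                        independence_method = "character",
                        independence_alpha = "numeric"))

setValidity("FilterConfig", function(object) {
  msg <- character()
  if (object@min_psi < 0 || object@min_psi > 1)
    msg <- c(msg, "min_psi must lie in [0, 1]")
  if (object@min_log2_cpm < 0 || object@min_cv < 0 ||
      object@min_samples_above_min_psi < 0 || object@min_non_missing < 0)
    msg <- c(msg, "thresholds must be non-negative")
  if (!object@independence_method %in% c("pcc", "pvalue"))
    msg <- c(msg, "independence_method must be 'pcc' or 'pvalue'")
  if (length(msg)) msg else TRUE
})

#' Create a FilterConfig
#'
#' Defaults reproduce the cohort eligibility rules of the screening
#' framework: genes with mean log2(CPM + 1) >= 1; events with PSI > 0.1 in
#' at least 100 samples, at least 100 non-missing values and CV(PSI) > 0.1;
#' RBP/modulator pairs with |r| <= 0.3 on log-expression.
#'
#' @param min_log2_cpm,min_psi,min_samples_above_min_psi,min_non_missing,min_cv,max_abs_pcc_independence,independence_method,independence_alpha
#'   see [FilterConfig-class].
#' @return A [FilterConfig-class] object.
#' @export
filterConfig <- function(min_log2_cpm = 1, min_psi = 0.1,
                         min_samples_above_min_psi = 100L,
                         min_non_missing = 100L, min_cv = 0.1,
                         max_abs_pcc_independence = 0.3,
                         independence_method = c("pcc", "pvalue"),
                         independence_alpha = 0.05) {
  new("FilterConfig",
      min_log2_cpm = min_log2_cpm, min_psi = min_psi,
      min_samples_above_min_psi = as.integer(min_samples_above_min_psi),
      min_non_missing = as.integer(min_non_missing), min_cv = min_cv,
      max_abs_pcc_independence = max_abs_pcc_independence,
      independence_method = match.arg(independence_method),
      independence_alpha = independence_alpha)
}

#' eCLIP peak-to-event mapping settings
#'
#' @slot min_enrichment minimum fold enrichment of a usable peak
#'   (inclusive; 8 corresponds to log2 fold change >= 3).
#' @slot max_pvalue peaks kept when their p-value is strictly below this.
#' @slot flank_bp window half-extension around the skipped exon, in bases.
#' @slot strand_specific when `TRUE`, peaks only support events on the same
#'   strand.
#' @export
setClass("MappingConfig",
         representation(min_enrichment = "numeric",
                        max_pvalue = "numeric",
                        flank_bp = "integer",
                        strand_specific = "logical"))

setValidity("MappingConfig", function(object) {
  msg <- character()
  if (object@flank_bp < 0) msg <- c(msg, "flank_bp must be >= 0")
  if (object@max_pvalue <= 0 || object@max_pvalue >= 1)
    msg <- c(msg, "max_pvalue must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Create a MappingConfig
#'
#' Defaults follow the eCLIP filtering recommendation: fold enrichment >= 8
#' (log2FC >= 3), p < 1e-5, and a window from 300 bp upstream to 300 bp
#' downstream of the skipped exon.
#'
#' @param min_enrichment,max_pvalue,flank_bp,strand_specific see
#'   [MappingConfig-class].
#' @return A [MappingConfig-class] object.
#' @export
mappingConfig <- function(min_enrichment = 8, max_pvalue = 1e-5,
                          flank_bp = 300L, strand_specific = FALSE) {
  new("MappingConfig", min_enrichment = min_enrichment,
      max_pvalue = max_pvalue, flank_bp = as.integer(flank_bp),
      strand_specific = strand_specific)
}

#' Interaction-screen settings
#'
#' @slot fdr Benjamini-Hochberg threshold on the interaction-term q-values.
#' @slot min_cell_count minimum retained samples in each of the four
#'   (rbp, modulator) label cells; undersized triplets are skipped.
#' @slot estimator `"proportions"` (difference-in-differences of inclusion
#'   proportions over the discretized design) or `"continuous-ols"`
#'   (ordinary least squares on raw values with a t-test on the interaction
#'   coefficient).
#' @export
setClass("ScreenConfig",
         representation(fdr = "numeric",
                        min_cell_count = "integer",
                        estimator = "character"))

setValidity("ScreenConfig", function(object) {
  msg <- character()
  if (object@fdr <= 0 || object@fdr >= 1)
    msg <- c(msg, "fdr must lie in (0, 1)")
  if (!object@estimator %in% c("proportions", "continuous-ols"))
    msg <- c(msg, "estimator must be 'proportions' or 'continuous-ols'")
  if (length(msg)) msg else TRUE
})

#' Create a ScreenConfig
#'
#' @param fdr,min_cell_count,estimator see [ScreenConfig-class].
#' @return A [ScreenConfig-class] object.
#' @export
screenConfig <- function(fdr = 0.01, min_cell_count = 5L,
                         estimator = c("proportions", "continuous-ols")) {
  new("ScreenConfig", fdr = fdr, min_cell_count = as.integer(min_cell_count),
      estimator = match.arg(estimator))
}

#' Synthetic-cohort settings
#'
#' The generator draws CPM-like log-normal expression for RBPs and modulator
#' candidates and generates each event's PSI through a logistic link on the
#' standardized log-expression of its binding RBP, with the modulator
#' entering through the interaction slope: `PSI = plogis(b0 + (b1 + b3 *
#' s_m) * s_r + eps)`.  Planted events carry a non-zero interaction; null
#' events have `b3 = 0`.
#'
#' @slot n_samples cohort size (default 480, the reference cohort size).
#' @slot n_rbps,n_modulators,n_events numbers of simulated RBPs, modulator
#'   candidates and skipped-exon events.
#' @slot fraction_planted fraction of events carrying one planted modulator.
#' @slot category_mix named proportions over the six modulation categories,
#'   summing to 1.
#' @slot plant_effects `"category"` (effect sizes from [plantCategory()]) or
#'   `"fixed"` (use `b0`, `b1`, `b3` for every planted event).
#' @slot b0 baseline logit of PSI.
#' @slot b1 main RBP slope on the logit scale.
#' @slot b3 interaction slope on the logit scale (used when
#'   `plant_effects = "fixed"`).
#' @slot noise_sd residual standard deviation on the logit scale.
#' @slot missing_rate fraction of PSI entries set missing, uniformly at
#'   random.
#' @slot seed integer RNG seed; the whole cohort is reproducible from it.
#' @export
setClass("SimConfig",
         representation(n_samples = "integer", n_rbps = "integer",
                        n_modulators = "integer", n_events = "integer",
                        fraction_planted = "numeric",
                        category_mix = "numeric",
                        plant_effects = "character",
                        b0 = "numeric", b1 = "numeric", b3 = "numeric",
                        noise_sd = "numeric", missing_rate = "numeric",
                        seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@n_samples < 3) msg <- c(msg, "n_samples must be >= 3")
  if (object@fraction_planted < 0 || object@fraction_planted > 1)
    msg <- c(msg, "fraction_planted must lie in [0, 1]")
  if (abs(sum(object@category_mix) - 1) > 1e-8)
    msg <- c(msg, "category_mix must sum to 1")
  if (!all(names(object@category_mix) %in% MODULATION_CATEGORIES))
    msg <- c(msg, "category_mix names must be the six modulation categories")
  if (object@noise_sd < 0) msg <- c(msg, "noise_sd must be >= 0")
  if (object@missing_rate < 0 || object@missing_rate >= 1)
    msg <- c(msg, "missing_rate must lie in [0, 1)")
  if (!object@plant_effects %in% c("category", "fixed"))
    msg <- c(msg, "plant_effects must be 'category' or 'fixed'")
  if (length(msg)) msg else TRUE
})

#' Create a SimConfig
#'
#' @param n_samples,n_rbps,n_modulators,n_events,fraction_planted,category_mix,plant_effects,b0,b1,b3,noise_sd,missing_rate,seed
#'   see [SimConfig-class].
#' @return A [SimConfig-class] object.
#' @export
simConfig <- function(n_samples = 480L, n_rbps = 5L, n_modulators = 20L,
                      n_events = 50L, fraction_planted = 0.3,
                      category_mix = NULL,
                      plant_effects = c("category", "fixed"),
                      b0 = 0, b1 = 0.5, b3 = 1, noise_sd = 1,
                      missing_rate = 0.1, seed = 1L) {
  if (is.null(category_mix))
    category_mix <- setNames(rep(1 / 6, 6), MODULATION_CATEGORIES)
  new("SimConfig", n_samples = as.integer(n_samples),
      n_rbps = as.integer(n_rbps), n_modulators = as.integer(n_modulators),
      n_events = as.integer(n_events), fraction_planted = fraction_planted,
      category_mix = category_mix, plant_effects = match.arg(plant_effects),
      b0 = b0, b1 = b1, b3 = b3, noise_sd = noise_sd,
      missing_rate = missing_rate, seed = as.integer(seed))
}

#' The six modulation categories
#'
#' Attenuates/enhances exon exclusion (AEE/EEE), attenuates/enhances exon
#' inclusion (AEI/EEI), inversion from inclusion to exclusion (ExonIE) and
#' from exclusion to inclusion (ExonEI).
#'
#' @format Character vector of length 6.
#' @export
MODULATION_CATEGORIES <- c("AEE", "AEI", "EEE", "EEI", "ExonIE", "ExonEI")

# integer codes used in the pattern matrix (0 = absent)
.CATEGORY_CODES <- setNames(1:6, MODULATION_CATEGORIES)
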