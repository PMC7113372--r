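#' @importFrom stats setNames
NULL

#' Accessors for spliceMod containers
#'
#' `geneIds`, `sampleIds` and `eventIds` return the identifier vectors of
#' the core containers; `eventRecords` the event table of a catalog;
#' `targetTable` the (rbp, event, n_support) table of a target map; `rbps`
#' and `targetEvents` query a target map.
#'
#' @param x a spliceMod container.
#' @param rbp an RBP identifier.
#' @return Character vectors (identifiers) or data.frames (tables).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setGeneric("eventIds", function(x) standardGeneric("eventIds"))

#' @rdname accessors
#' @export
setGeneric("eventRecords", function(x) standardGeneric("eventRecords"))

#' @rdname accessors
#' @export
setGeneric("targetTable", function(x) standardGeneric("targetTable"))

#' @rdname accessors
#' @export
setGeneric("rbps", function(x) standardGeneric("rbps"))

#' @rdname accessors
#' @export
setGeneric("targetEvents", function(x, rbp) standardGeneric("targetEvents"))

#' @rdname accessors
#' @export
setMethod("geneIds", "ExpressionMatrix", function(x) rownames(x))

#' @rdname accessors
#' @export
setMethod("sampleIds", "ExpressionMatrix", function(x) colnames(x))

#' @rdname accessors
#' @export
setMethod("eventIds", "PsiMatrix", function(x) rownames(x))

#' @rdname accessors
#' @export
setMethod("sampleIds", "PsiMatrix", function(x) colnames(x))

#' @rdname accessors
#' @export
setMethod("eventIds", "SpliceEventCatalog", function(x) x@events$event_id)

#' @rdname accessors
#' @export
setMethod("eventRecords", "SpliceEventCatalog", function(x) x@events)

#' @rdname accessors
#' @export
setMethod("targetTable", "RbpTargetMap", function(x) x@map)

#' @rdname accessors
#' @export
setMethod("rbps", "RbpTargetMap", function(x) sort(unique(x@map$rbp)))

#' @rdname accessors
#' @export
setMethod("targetEvents", "RbpTargetMap", function(x, rbp) {
  x@map$event_id[x@map$rbp == rbp]
})

#' @rdname accessors
#' @export
setMethod("length", "SpliceEventCatalog", function(x) nrow(x@events))

#' Subset a splice-event catalog
#'
#' @param x a [SpliceEventCatalog-class].
#' @param i numeric, logical or character (event id) index.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "SpliceEventCatalog", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@events$event_id)
  SpliceEventCatalog(x@events[i, , drop = FALSE])
})

#' Cohort component accessors
#'
#' @param x a [TripletCohort-class].
#' @return The stored component.
#' @name cohort-accessors
NULL

#' @rdname cohort-accessors
#' @export
setGeneric("cohortExpr", function(x) standardGeneric("cohortExpr"))
#' @rdname cohort-accessors
#' @export
setGeneric("cohortPsi", function(x) standardGeneric("cohortPsi"))
#' @rdname cohort-accessors
#' @export
setGeneric("cohortEvents", function(x) standardGeneric("cohortEvents"))
#' @rdname cohort-accessors
#' @export
setGeneric("cohortTargets", function(x) standardGeneric("cohortTargets"))
#' @rdname cohort-accessors
#' @export
setGeneric("cohortTruth", function(x) standardGeneric("cohortTruth"))

#' @rdname cohort-accessors
#' @export
setMethod("cohortExpr", "TripletCohort", function(x) x@expr)
#' @rdname cohort-accessors
#' @export
setMethod("cohortPsi", "TripletCohort", function(x) x@psi)
#' @rdname cohort-accessors
#' @export
setMethod("cohortEvents", "TripletCohort", function(x) x@events)
#' @rdname cohort-accessors
#' @export
setMethod("cohortTargets", "TripletCohort", function(x) x@targets)
#' @rdname cohort-accessors
#' @export
setMethod("cohortTruth", "TripletCohort", function(x) x@truth)

# ---- show methods -----------------------------------------------------------

setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples (CPM)\n",
              nrow(object), ncol(object)))
})

setMethod("show", "PsiMatrix", function(object) {
  n_na <- sum(is.na(object@.Data))
  cat(sprintf("PsiMatrix: %d events x %d samples, %d missing (%.1f%%)\n",
              nrow(object), ncol(object), n_na,
              100 * n_na / max(1, length(object@.Data))))
})

setMethod("show", "SpliceEventCatalog", function(object) {
  cat(sprintf("SpliceEventCatalog: %d skipped-exon events on %d chromosome(s)\n",
              nrow(object@events), length(unique(object@events$chrom))))
})

setMethod("show", "RbpTargetMap", function(object) {
  cat(sprintf("RbpTargetMap: %d RBPs, %d (rbp, event) assignments\n",
              length(unique(object@map$rbp)), nrow(object@map)))
})

setMethod("show", "TripletCohort", function(object) {
  cat("TripletCohort\n")
  cat(sprintf("  expression: %d genes x %d samples\n",
              nrow(object@expr), ncol(object@expr)))
  cat(sprintf("  PSI: %d events x %d samples\n",
              nrow(object@psi), ncol(object@psi)))
  cat(sprintf("  targets: %d assignments; truth rows: %d (%d planted)\n",
              nrow(object@targets@map), nrow(object@truth),
              sum(object@truth$planted)))
})

setMethod("show", "FilterConfig", function(object) {
  cat(sprintf(paste0("FilterConfig: mean log2(CPM+1) >= %g; PSI > %g in >= %d",
                     " samples; >= %d non-missing; CV > %g; |r| <= %g (%s)\n"),
              object@min_log2_cpm, object@min_psi,
              object@min_samples_above_min_psi, object@min_non_missing,
              object@min_cv, object@max_abs_pcc_independence,
              object@independence_method))
})

setMethod("show", "MappingConfig", function(object) {
  cat(sprintf("MappingConfig: enrichment >= %g, p < %g, flank %d bp%s\n",
              object@min_enrichment, object@max_pvalue, object@flank_bp,
              if (object@strand_specific) ", strand-specific" else ""))
})

setMethod("show", "ScreenConfig", function(object) {
  cat(sprintf("ScreenConfig: BH fdr <= %g, min cell count %d, estimator %s\n",
              object@fdr, object@min_cell_count, object@estimator))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(paste0("SimConfig: %d samples, %d RBPs, %d modulators, %d events;",
                     " planted %.0f%% (%s); b0=%g b1=%g b3=%g noise_sd=%g;",
                     " missing %.0f%%; seed %d\n"),
              object@n_samples, object@n_rbps, object@n_modulators,
              object@n_events, 100 * object@fraction_planted,
              object@plant_effects, object@b0, object@b1, object@b3,
              object@noise_sd, 100 * object@missing_rate, object@seed))
})
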