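#' @name accessors
#' @title Accessors for clonequant S4 classes
#' @description Small accessor generics: prefer these over direct slot access.
#' @param x an object of the documented class.
NULL

#' @rdname accessors
#' @export
setGeneric("vectorInfo", function(x) standardGeneric("vectorInfo"))
#' @rdname accessors
#' @export
setMethod("vectorInfo", "VectorSet", function(x) x@info)

#' @rdname accessors
#' @export
setGeneric("poolProportions", function(x) standardGeneric("poolProportions"))
#' @rdname accessors
#' @export
setMethod("poolProportions", "VectorSet", function(x) x@proportions)

#' @rdname accessors
#' @export
setGeneric("sgids", function(x) standardGeneric("sgids"))
#' @rdname accessors
#' @export
setMethod("sgids", "VectorSet", function(x) x@info$sgID)

#' @rdname accessors
#' @export
setGeneric("tumors", function(x) standardGeneric("tumors"))
#' @rdname accessors
#' @export
setMethod("tumors", "TumorSet", function(x) x@tumors)
#' @rdname accessors
#' @export
setMethod("tumors", "SyntheticTruth", function(x) x@truth)

#' @rdname accessors
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))
#' @rdname accessors
#' @export
setMethod("sampleInfo", "TumorSet", function(x) x@samples)
#' @rdname accessors
#' @export
setMethod("sampleInfo", "SyntheticTruth", function(x) x@samples)

#' @rdname accessors
#' @export
setGeneric("quotas", function(x) standardGeneric("quotas"))
#' @rdname accessors
#' @export
setMethod("quotas", "SamplingPlan", function(x) x@quotas)

#' @rdname accessors
#' @export
setGeneric("allocations", function(x) standardGeneric("allocations"))
#' @rdname accessors
#' @export
setMethod("allocations", "SamplingPlan", function(x) x@allocations)

#' @rdname accessors
#' @export
setGeneric("benchmarkInfo", function(x) standardGeneric("benchmarkInfo"))
#' @rdname accessors
#' @export
setMethod("benchmarkInfo", "SamplingPlan", function(x) x@benchmark)

#' @rdname accessors
#' @export
setGeneric("modelTable", function(x) standardGeneric("modelTable"))
#' @rdname accessors
#' @export
setMethod("modelTable", "ContaminationModel", function(x) x@table)

setMethod("show", "VectorSet", function(object) {
  info <- object@info
  cat("VectorSet with", nrow(info), "vectors:",
      paste(sprintf("%d %s", table(info$class), names(table(info$class))),
            collapse = ", "), "\n")
  if (nrow(object@proportions))
    cat("  pool proportions for cohorts:",
        paste(unique(object@proportions$cohort), collapse = ", "), "\n")
})

setMethod("show", "TumorSet", function(object) {
  cat("TumorSet:", nrow(object@tumors), "tumor records across",
      nrow(object@samples), "samples\n")
  if (nrow(object@samples))
    cat("  cohorts:", paste(unique(object@samples$cohort), collapse = ", "), "\n")
  if (nrow(object@tumors))
    cat("  cells calibrated:", !all(is.na(object@tumors$cells)), "\n")
})

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth:", nrow(object@truth), "tumors in",
      nrow(object@samples), "mice\n")
})

setMethod("show", "SamplingPlan", function(object) {
  b <- object@benchmark
  cat(sprintf("SamplingPlan benchmarked on %s in cohort %s (n = %d)\n",
              b$sgID, b$cohort, b$n))
  cat("  quotas for", nrow(object@quotas), "(cohort, sgID) pairs\n")
  if (nrow(object@allocations))
    cat("  allocated across mice\n")
})

setMethod("show", "ContaminationModel", function(object) {
  cat(sprintf("ContaminationModel (%s %.1f%% quantile) for %d sgIDs\n",
              if (object@truncated) "zero-truncated" else "untruncated",
              100 * object@quantile, nrow(object@table)))
})

#' Subset a TumorSet by sample or by a logical/integer index on tumors
#'
#' @param x a [TumorSet-class].
#' @param samples character vector of sample ids to keep (default all).
#' @param which logical or integer index on tumor rows (default all).
#' @return a [TumorSet-class] restricted to the requested records; sample
#'   metadata is kept for the retained samples only.
#' @export
subsetTumors <- function(x, samples = NULL, which = NULL) {
  stopifnot(is(x, "TumorSet"))
  tu <- x@tumors
  sa <- x@samples
  if (!is.null(which)) tu <- tu[which, , drop = FALSE]
  if (!is.null(samples)) {
    tu <- tu[tu$sample %in% samples, , drop = FALSE]
    sa <- sa[sa$sample %in% samples, , drop = FALSE]
  }
  rownames(tu) <- NULL
  rownames(sa) <- NULL
  new("TumorSet", tumors = tu, samples = sa)
}
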