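#' QC admission thresholds
#'
#' Defaults follow the cohort admission rules used for real tumor-barcoding
#' cohorts: mice with fewer than 1,000 unique barcodes are deemed
#' unsuccessfully transduced; vectors with fewer than 3,000 unique barcodes
#' pooled across the experimental cohorts are insufficiently represented
#' (corroborated when the Cas9-negative control shows fewer than 750); and
#' benchmark tumor counting requires at least 5 supporting reads. All
#' comparisons are strict `<` ("fewer than"): a count exactly at threshold
#' is retained.
#'
#' @param min_barcodes_per_mouse,min_barcodes_per_vector_experimental,min_barcodes_per_vector_control,min_reads_support
#'   positive integer thresholds.
#' @return a named list of thresholds.
#' @export
qcThresholds <- function(min_barcodes_per_mouse = 1000L,
                         min_barcodes_per_vector_experimental = 3000L,
                         min_barcodes_per_vector_control = 750L,
                         min_reads_support = 5L) {
  th <- list(min_barcodes_per_mouse = as.integer(min_barcodes_per_mouse),
             min_barcodes_per_vector_experimental =
               as.integer(min_barcodes_per_vector_experimental),
             min_barcodes_per_vector_control =
               as.integer(min_barcodes_per_vector_control),
             min_reads_support = as.integer(min_reads_support))
  stopifnot(all(unlist(th) > 0L))
  th
}

#' Remove samples with aberrantly few barcodes
#'
#' @param ts a [TumorSet-class] (post-collapse, post-contamination-filter).
#' @param thresholds from [qcThresholds()].
#' @return list with `tumors` (retained samples) and `report` (data.frame of
#'   all samples with barcode counts and retained flag).
#' @export
filterMice <- function(ts, thresholds = qcThresholds()) {
  sa <- sampleInfo(ts)
  tu <- tumors(ts)
  if (!nrow(sa)) {
    warning("empty cohort: no samples to filter")
    return(list(tumors = ts,
                report = data.frame(sample = character(0),
                                    n_barcodes = integer(0),
                                    retained = logical(0))))
  }
  counts <- vapply(sa$sample, function(s)
    length(unique(tu$barcode[tu$sample == s])), integer(1))
  retained <- counts >= thresholds$min_barcodes_per_mouse
  report <- data.frame(sample = sa$sample, n_barcodes = counts,
                       retained = retained, row.names = NULL)
  list(tumors = subsetTumors(ts, samples = sa$sample[retained]),
       report = report)
}

#' Remove vectors with insufficient titer
#'
#' A vector is excluded when its unique-barcode count pooled across the
#' experimental cohorts falls below the experimental threshold. When a
#' Cas9-negative control set is supplied, the report notes whether control
#' representation corroborates the exclusion (also below the control
#' threshold) or conflicts with it; a conflict still excludes, but is
#' flagged for manual review.
#'
#' @param ts experimental [TumorSet-class] (young + aged pooled).
#' @param control optional control-cohort [TumorSet-class].
#' @param thresholds from [qcThresholds()].
#' @return list with `tumors` (retained vectors), `report` (per-vector
#'   counts, retained flag, control corroboration).
#' @export
filterVectors <- function(ts, control = NULL, thresholds = qcThresholds()) {
  tu <- tumors(ts)
  sg <- unique(tu$sgID)
  counts <- vapply(sg, function(g)
    length(unique(tu$barcode[tu$sgID == g])), integer(1))
  retained <- counts >= thresholds$min_barcodes_per_vector_experimental
  control_counts <- rep(NA_integer_, length(sg))
  if (!is.null(control)) {
    ctu <- tumors(control)
    control_counts <- vapply(sg, function(g)
      length(unique(ctu$barcode[ctu$sgID == g])), integer(1))
  }
  status <- rep("retained", length(sg))
  status[!retained] <- ifelse(
    is.na(control_counts[!retained]), "excluded",
    ifelse(control_counts[!retained] <
             thresholds$min_barcodes_per_vector_control,
           "excluded_corroborated", "excluded_conflict"))
  if (any(status == "excluded_conflict"))
    warning("vector(s) well-represented in control but poor in experimental ",
            "cohorts: ", paste(sg[status == "excluded_conflict"],
                               collapse = ", "),
            " (excluded; flagged for review)")
  report <- data.frame(sgID = sg, n_barcodes = counts,
                       control_barcodes = control_counts,
                       retained = retained, status = status,
                       row.names = NULL)
  list(tumors = subsetTumors(ts, which = tu$sgID %in% sg[retained]),
       report = report)
}

#' Apply mouse- and vector-level admission filters together
#'
#' Computes barcode tallies once on the input, then removes failing samples
#' and failing vectors simultaneously; because both decisions are taken on
#' the same tallies, mouse-then-vector and vector-then-mouse orders give
#' identical results.
#'
#' @param ts experimental [TumorSet-class].
#' @param control optional Cas9-negative control [TumorSet-class].
#' @param thresholds from [qcThresholds()].
#' @return list with `tumors`, `mouse_report`, `vector_report`.
#' @export
applyQcFilters <- function(ts, control = NULL, thresholds = qcThresholds()) {
  mice <- filterMice(ts, thresholds)
  vecs <- filterVectors(ts, control = control, thresholds = thresholds)
  keep_samples <- mice$report$sample[mice$report$retained]
  keep_sgids <- vecs$report$sgID[vecs$report$retained]
  tu <- tumors(ts)
  out <- subsetTumors(ts, samples = keep_samples,
                      which = tu$sgID %in% keep_sgids)
  list(tumors = out, mouse_report = mice$report,
       vector_report = vecs$report)
}
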