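#' VectorSet: the lentiviral vector (sgRNA) table
#'
#' Describes the Lenti-sgRNA/Cre pool: one row per vector with its 8-nt sgID,
#' sgRNA name, target gene, and functional class, plus (optionally) the
#' per-cohort pool proportions. Validity enforces the sequencing-design
#' constraints: sgIDs are 8-nt A/C/G/T strings separated pairwise by at least
#' three mismatches (so that sequencing error cannot flip one sgID into
#' another), and pool proportions sum to one per cohort over non-spike-in
#' vectors.
#'
#' @slot info data.frame with columns `sgID`, `sgRNA`, `gene`, `class`
#'   (one of targeting/inert/safe/essential/spike_in).
#' @slot proportions data.frame with columns `cohort`, `sgID`, `p`; may have
#'   zero rows when proportions are estimated later from Cas9-negative mice.
#' @export
setClass("VectorSet", representation(
  info = "data.frame",
  proportions = "data.frame"
))

setValidity("VectorSet", function(object) {
  info <- object@info
  need <- c("sgID", "sgRNA", "gene", "class")
  if (!all(need %in% names(info)))
    return(paste("info must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(info$sgID)) return("duplicate sgIDs")
  if (!all(nchar(info$sgID) == 8L) || !all(grepl("^[ACGT]{8}$", info$sgID)))
    return("sgIDs must be 8-nt A/C/G/T strings")
  ok <- c("targeting", "inert", "safe", "essential", "spike_in")
  if (!all(info$class %in% ok))
    return(paste("class must be one of", paste(ok, collapse = "/")))
  coll <- .sgidCollision(info$sgID)
  if (!is.null(coll))
    return(sprintf("sgID collision (fewer than 3 mismatches): %s vs %s",
                   coll[1], coll[2]))
  pr <- object@proportions
  if (nrow(pr)) {
    if (!all(c("cohort", "sgID", "p") %in% names(pr)))
      return("proportions must have columns cohort, sgID, p")
    if (!all(pr$sgID %in% info$sgID)) return("proportions reference unknown sgIDs")
    spikes <- info$sgID[info$class == "spike_in"]
    for (co in unique(pr$cohort)) {
      s <- sum(pr$p[pr$cohort == co & !(pr$sgID %in% spikes)])
      if (abs(s - 1) > 1e-6)
        return(sprintf("pool proportions for cohort '%s' sum to %.6f, not 1", co, s))
    }
  }
  TRUE
})

#' Construct a VectorSet
#'
#' @param info data.frame with columns `sgID`, `sgRNA`, `gene`, `class`.
#' @param proportions optional data.frame with columns `cohort`, `sgID`, `p`.
#' @return a validated [VectorSet-class] object.
#' @export
VectorSet <- function(info, proportions = NULL) {
  if (is.null(proportions))
    proportions <- data.frame(cohort = character(0), sgID = character(0),
                              p = numeric(0))
  info <- as.data.frame(info)
  rownames(info) <- NULL
  new("VectorSet", info = info, proportions = as.data.frame(proportions))
}

#' TumorSet: tumor records plus sample metadata
#'
#' The central container of the pipeline. `tumors` holds one row per putative
#' clonal expansion (sample, sgID, 30-nt cassette barcode, read count, and --
#' once spike-in calibrated -- absolute neoplastic cell number). `samples`
#' holds per-mouse metadata: cohort, age group, delivered titer (infectious
#' units) and Cas9 status.
#'
#' @slot tumors data.frame with columns `sample`, `sgID`, `barcode`, `reads`,
#'   `cells` (`cells` may be NA before spike-in calibration).
#' @slot samples data.frame with columns `sample`, `cohort`, `age_group`,
#'   `titer`, `cas9`.
#' @export
setClass("TumorSet", representation(
  tumors = "data.frame",
  samples = "data.frame"
))

setValidity("TumorSet", function(object) {
  tu <- object@tumors
  sa <- object@samples
  need <- c("sample", "sgID", "barcode", "reads", "cells")
  if (!all(need %in% names(tu)))
    return(paste("tumors must have columns", paste(need, collapse = ", ")))
  needs <- c("sample", "cohort", "age_group", "titer", "cas9")
  if (!all(needs %in% names(sa)))
    return(paste("samples must have columns", paste(needs, collapse = ", ")))
  if (anyDuplicated(sa$sample)) return("duplicate sample ids")
  if (nrow(tu)) {
    if (!all(tu$sample %in% sa$sample))
      return("tumor records reference samples absent from metadata")
    if (any(tu$reads < 0)) return("negative read counts")
    if (any(!is.na(tu$cells) & tu$cells < 0)) return("negative cell numbers")
  }
  if (any(sa$titer <= 0)) return("titers must be positive")
  TRUE
})

#' Construct a TumorSet
#'
#' @param tumors data.frame of tumor records (`sample`, `sgID`, `barcode`,
#'   `reads`, optionally `cells`).
#' @param samples data.frame of sample metadata (`sample`, `cohort`,
#'   `age_group`, `titer`, `cas9`).
#' @return a validated [TumorSet-class] object.
#' @export
TumorSet <- function(tumors, samples) {
  tumors <- as.data.frame(tumors)
  if (!"cells" %in% names(tumors)) tumors$cells <- NA_real_
  rownames(tumors) <- NULL
  samples <- as.data.frame(samples)
  rownames(samples) <- NULL
  new("TumorSet", tumors = tumors, samples = samples)
}

#' SyntheticTruth: a simulated cohort with known ground truth
#'
#' @slot truth data.frame with one row per simulated tumor: `sample`,
#'   `cohort`, `sgID`, `gene`, `barcode` (30-nt cassette), `cells`.
#' @slot samples sample metadata as in [TumorSet-class].
#' @slot pool list with the vector table, per-vector barcode sets and
#'   spike-in definitions produced by [generatePool()].
#' @slot config the generating truth configuration.
#' @export
setClass("SyntheticTruth", representation(
  truth = "data.frame",
  samples = "data.frame",
  pool = "list",
  config = "list"
))

#' SamplingPlan: adaptive-sampling quotas and per-mouse allocations
#'
#' @slot benchmark list with `sgID`, `cohort`, `n`: the benchmark vector,
#'   cohort and tumor count every other quota is scaled from.
#' @slot quotas data.frame with columns `cohort`, `sgID`, `n`.
#' @slot allocations data.frame with columns `cohort`, `sgID`, `sample`, `n`;
#'   zero rows until [allocateAcrossMice()] has been applied.
#' @export
setClass("SamplingPlan", representation(
  benchmark = "list",
  quotas = "data.frame",
  allocations = "data.frame"
))

setValidity("SamplingPlan", function(object) {
  q <- object@quotas
  if (!all(c("cohort", "sgID", "n") %in% names(q)))
    return("quotas must have columns cohort, sgID, n")
  if (any(q$n < 0)) return("quotas must be non-negative")
  b <- object@benchmark
  if (!all(c("sgID", "cohort", "n") %in% names(b)))
    return("benchmark must name sgID, cohort and n")
  TRUE
})

#' ContaminationModel: per-vector barcode recurrence model
#'
#' For each sgID, a zero-truncated Poisson model of how many samples a
#' barcode is observed in: `mu_nonzero` is the mean number of samples per
#' observed barcode, `lambda` the underlying Poisson rate solving
#' lambda/(1 - exp(-lambda)) = mu_nonzero, and `n_r` the smallest integer
#' containing the configured quantile of the recurrence distribution.
#'
#' @slot table data.frame with columns `sgID`, `mu_nonzero`, `lambda`, `n_r`.
#' @slot quantile the recurrence quantile (default 0.999).
#' @slot truncated logical; whether the quantile conditions on k >= 1.
#' @export
setClass("ContaminationModel", representation(
  table = "data.frame",
  quantile = "numeric",
  truncated = "logical"
))

setValidity("ContaminationModel", function(object) {
  tb <- object@table
  if (!all(c("sgID", "mu_nonzero", "lambda", "n_r") %in% names(tb)))
    return("table must have columns sgID, mu_nonzero, lambda, n_r")
  if (any(tb$mu_nonzero < 1)) return("mu_nonzero must be >= 1")
  if (any(tb$lambda < 0)) return("lambda must be >= 0")
  if (any(tb$n_r < 1)) return("n_r must be >= 1")
  # the solver identity must hold where lambda > 0
  pos <- tb$lambda > 1e-8
  if (any(pos)) {
    res <- tb$lambda[pos] / (1 - exp(-tb$lambda[pos])) - tb$mu_nonzero[pos]
    if (any(abs(res) > 1e-6)) return("lambda inconsistent with mu_nonzero")
  }
  TRUE
})
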