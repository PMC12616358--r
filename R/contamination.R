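#' Solve the zero-truncated Poisson rate from the observed mean
#'
#' Barcode recurrence across samples is modeled as Poisson with rate
#' `lambda`; only barcodes observed at least once are seen, so the observed
#' mean number of samples per barcode is the zero-truncated mean
#' `lambda / (1 - exp(-lambda))`. This inverts that strictly increasing map.
#'
#' @param mu_nonzero observed mean occurrences per barcode (>= 1).
#' @param tol residual tolerance on the truncated-mean identity.
#' @return the unique `lambda > 0` solving the identity, or 0 when
#'   `mu_nonzero` is within `tol` of 1 (the limit case).
#' @export
estimateLambda <- function(mu_nonzero, tol = 1e-10) {
  if (length(mu_nonzero) > 1L)
    return(vapply(mu_nonzero, estimateLambda, numeric(1), tol = tol))
  if (is.na(mu_nonzero) || mu_nonzero < 1)
    .stopData("mu_nonzero < 1 is impossible for observed barcodes (got ",
              mu_nonzero, ")")
  if (mu_nonzero <= 1 + tol) return(0)
  f <- function(l) l / (-expm1(-l)) - mu_nonzero
  upper <- max(2 * mu_nonzero, 1)
  while (f(upper) < 0) upper <- upper * 2
  uniroot(f, c(1e-12, upper), tol = tol * 1e-2)$root
}

#' Recurrence threshold from the Poisson rate
#'
#' The smallest integer `n` such that the configured quantile (default
#' 99.9%) of the barcode-recurrence distribution is at most `n` samples.
#' By default the quantile is taken on the zero-truncated Poisson
#' (conditioning on k >= 1, matching how `mu_nonzero` is estimated from
#' observed barcodes); the untruncated quantile is available.
#'
#' @param lambda Poisson rate (>= 0).
#' @param quantile target quantile (default 0.999).
#' @param truncated condition on k >= 1 (default TRUE).
#' @return integer threshold `N_r >= 1`.
#' @export
recurrenceThreshold <- function(lambda, quantile = 0.999, truncated = TRUE) {
  if (length(lambda) > 1L)
    return(vapply(lambda, recurrenceThreshold, integer(1),
                  quantile = quantile, truncated = truncated))
  stopifnot(lambda >= 0)
  if (lambda < 1e-12) return(1L)
  n <- 1L
  repeat {
    mass <- if (truncated) {
      (ppois(n, lambda) - dpois(0, lambda)) / (1 - dpois(0, lambda))
    } else {
      ppois(n, lambda)
    }
    if (mass >= quantile) return(n)
    n <- n + 1L
    if (n > 10000L) .stopData("recurrence threshold did not converge")
  }
}

#' Fit per-vector contamination models from cross-sample recurrence
#'
#' For each sgID, counts in how many samples each barcode is present
#' (any reads > 0, computed after spurious-barcode collapse), estimates
#' `mu_nonzero` as the mean, solves for `lambda`, and derives the
#' recurrence threshold `N_r`.
#'
#' @param ts a [TumorSet-class] covering all samples of the sequencing batch.
#' @param quantile recurrence quantile (default 0.999).
#' @param truncated use the zero-truncated quantile (default TRUE; the
#'   choice is recorded in the returned object).
#' @return a [ContaminationModel-class].
#' @export
fitContaminationModels <- function(ts, quantile = 0.999, truncated = TRUE) {
  tu <- tumors(ts)
  dt <- data.table::as.data.table(tu[tu$reads > 0, c("sample", "sgID",
                                                     "barcode")])
  occ <- dt[, list(n_samples = data.table::uniqueN(sample)),
            by = c("sgID", "barcode")]
  tab <- occ[, list(mu_nonzero = mean(n_samples)), by = "sgID"]
  tab <- as.data.frame(tab)
  tab$lambda <- estimateLambda(tab$mu_nonzero)
  tab$n_r <- recurrenceThreshold(tab$lambda, quantile = quantile,
                                 truncated = truncated)
  new("ContaminationModel", table = tab, quantile = quantile,
      truncated = truncated)
}

#' Remove contaminating barcodes by recurrence, with dominant-sample rescue
#'
#' A barcode present in more samples than its vector's threshold `N_r` is
#' judged contamination -- unless a single sample holds strictly more than
#' the rescue share (default 95%) of its pooled reads, in which case the
#' barcode is retained in that dominant sample only (index hopping from one
#' very large tumor) and removed elsewhere. Barcodes at or below `N_r` are
#' untouched. The filter is idempotent for a fixed model.
#'
#' @param ts a [TumorSet-class].
#' @param model a [ContaminationModel-class] fit on the same batch.
#' @param rescue_share dominant-sample read share (strict `>`; default 0.95).
#' @return list with `tumors` (filtered [TumorSet-class]) and `log`
#'   (data.frame: `sgID`, `barcode`, `n_samples`, `max_share`, `action`).
#' @export
applyRecurrenceFilter <- function(ts, model, rescue_share = 0.95) {
  tu <- tumors(ts)
  mt <- modelTable(model)
  dt <- data.table::as.data.table(tu)
  stat <- dt[reads > 0,
             list(n_samples = data.table::uniqueN(sample),
                  total_reads = sum(reads),
                  max_reads = max(reads),
                  max_sample = sample[which.max(reads)]),
             by = c("sgID", "barcode")]
  stat$n_r <- mt$n_r[match(stat$sgID, mt$sgID)]
  stat$n_r[is.na(stat$n_r)] <- 1L
  flagged <- stat[stat$n_samples > stat$n_r]
  if (!nrow(flagged)) {
    log <- data.frame(sgID = character(0), barcode = character(0),
                      n_samples = integer(0), max_share = numeric(0),
                      action = character(0))
    return(list(tumors = ts, log = log))
  }
  flagged$max_share <- flagged$max_reads / flagged$total_reads
  flagged$action <- ifelse(flagged$max_share > rescue_share,
                           "rescued_dominant", "removed")
  key_all <- paste(tu$sgID, tu$barcode)
  key_flagged <- paste(flagged$sgID, flagged$barcode)
  hit <- match(key_all, key_flagged)
  drop <- !is.na(hit) &
    !(flagged$action[hit] == "rescued_dominant" &
        tu$sample == flagged$max_sample[hit])
  out <- subsetTumors(ts, which = !drop)
  log <- as.data.frame(flagged[, c("sgID", "barcode", "n_samples",
                                   "max_share", "action")])
  list(tumors = out, log = log)
}
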