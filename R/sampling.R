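#' Estimate pool proportions from a Cas9-negative control cohort
#'
#' In Cas9-negative mice every vector is functionally inert, so the number
#' of unique barcodes (tumors) per sgID reflects the make-up of the viral
#' pool. Proportions are normalized over the retained vectors.
#'
#' @param control a [TumorSet-class] of Cas9-negative samples.
#' @param sgids optional character vector restricting/ordering the vectors.
#' @return data.frame with columns `sgID`, `p` (summing to 1).
#' @export
estimatePoolProportions <- function(control, sgids = NULL) {
  if (is.null(control) || !nrow(tumors(control)))
    .stopData("no Cas9-negative control data: supply pool proportions ",
              "explicitly")
  sa <- sampleInfo(control)
  if (any(sa$cas9))
    warning("control TumorSet contains Cas9-positive samples; proportions ",
            "assume functional inertness")
  tu <- tumors(control)
  if (is.null(sgids)) sgids <- sort(unique(tu$sgID))
  counts <- vapply(sgids, function(g)
    length(unique(tu$barcode[tu$sgID == g])), integer(1))
  if (sum(counts) == 0) .stopData("control cohort has no tumors")
  data.frame(sgID = sgids, p = counts / sum(counts), row.names = NULL)
}

#' Compute per-sgRNA, per-cohort adaptive-sampling quotas
#'
#' Scales a benchmark tumor count so that every (sgRNA, cohort) pair
#' contributes the same number of tumors per infectious unit of virus
#' delivered:
#' `N[i, j] = N_bench * (T[j] / T[bench]) * (p[i, j] / p[bench])`,
#' rounded half-to-even to an integer. The benchmark entry equals
#' `n_benchmark` exactly.
#'
#' @param benchmark_sgid,benchmark_cohort the benchmark vector and cohort.
#' @param n_benchmark tumors sampled for the benchmark entry (> 0).
#' @param cohorts data.frame with columns `cohort`, `titer_total` (total
#'   infectious units delivered to the cohort, summed over its mice).
#' @param proportions data.frame `sgID`, `p` (shared across cohorts) or
#'   `cohort`, `sgID`, `p` (per cohort).
#' @return a [SamplingPlan-class] with quotas (allocations empty).
#' @export
computeSamplingPlan <- function(benchmark_sgid, benchmark_cohort, n_benchmark,
                                cohorts, proportions) {
  stopifnot(n_benchmark > 0)
  if (!"cohort" %in% names(proportions)) {
    proportions <- do.call(rbind, lapply(cohorts$cohort, function(co)
      data.frame(cohort = co, sgID = proportions$sgID, p = proportions$p)))
  }
  pb <- proportions$p[proportions$cohort == benchmark_cohort &
                        proportions$sgID == benchmark_sgid]
  tb <- cohorts$titer_total[cohorts$cohort == benchmark_cohort]
  if (!length(pb) || pb == 0)
    .stopData("benchmark sgRNA has zero or missing pool proportion; ",
              "the plan is undefined")
  if (!length(tb)) .stopData("benchmark cohort absent from cohort table")
  q <- proportions
  q$titer <- cohorts$titer_total[match(q$cohort, cohorts$cohort)]
  q$n <- as.integer(round(n_benchmark * (q$titer / tb) * (q$p / pb)))
  q$n[q$cohort == benchmark_cohort & q$sgID == benchmark_sgid] <-
    as.integer(n_benchmark)
  quotas <- q[, c("cohort", "sgID", "n")]
  rownames(quotas) <- NULL
  new("SamplingPlan",
      benchmark = list(sgID = benchmark_sgid, cohort = benchmark_cohort,
                       n = as.integer(n_benchmark)),
      quotas = quotas,
      allocations = data.frame(cohort = character(0), sgID = character(0),
                               sample = character(0), n = integer(0)))
}

#' Largest-remainder integer apportionment
#'
#' Distributes `n` proportionally to `weights`, flooring and then assigning
#' leftover units to the largest fractional remainders (ties broken by
#' position, deterministically).
#'
#' @param n total to distribute (non-negative integer).
#' @param weights non-negative weights, at least one positive.
#' @return integer vector summing to `n`.
#' @export
largestRemainder <- function(n, weights) {
  stopifnot(n >= 0, length(weights) >= 1L, all(weights >= 0),
            any(weights > 0))
  raw <- n * weights / sum(weights)
  fl <- floor(raw)
  left <- as.integer(round(n - sum(fl)))
  if (left > 0L) {
    ord <- order(raw - fl, decreasing = TRUE)[seq_len(left)]
    fl[ord] <- fl[ord] + 1
  }
  as.integer(fl)
}

#' Allocate a per-cohort quota across mice
#'
#' Quotas are split across mice in proportion to the total number of tumors
#' in each mouse (largest-remainder integerization). A mouse lacking enough
#' tumors of the sgRNA is capped at availability and the shortfall
#' redistributed to the remaining mice by the same proportional rule (one
#' pass), then truncated with a warning if the cohort as a whole lacks
#' tumors.
#'
#' @param n quota for one (sgRNA, cohort) pair.
#' @param mouse_totals named numeric: total tumors per mouse (all sgRNAs;
#'   the allocation weight).
#' @param available named integer: tumors of this sgRNA available per mouse
#'   (defaults to unlimited).
#' @return named integer vector of per-mouse quotas.
#' @export
allocateAcrossMice <- function(n, mouse_totals, available = NULL) {
  stopifnot(!is.null(names(mouse_totals)))
  if (is.null(available))
    available <- setNames(rep(.Machine$integer.max, length(mouse_totals)),
                          names(mouse_totals))
  available <- available[names(mouse_totals)]
  available[is.na(available)] <- 0L
  alloc <- largestRemainder(n, mouse_totals)
  names(alloc) <- names(mouse_totals)
  over <- alloc > available
  if (any(over)) {
    shortfall <- sum(alloc[over] - available[over])
    alloc[over] <- available[over]
    room <- !over & alloc < available
    if (shortfall > 0L && any(room)) {
      extra <- largestRemainder(shortfall, mouse_totals[room])
      alloc[room] <- alloc[room] + extra
      alloc <- pmin(alloc, available)
    }
    if (sum(alloc) < n)
      warning(sprintf(
        "available tumors (%d) fall short of quota %d; truncated",
        sum(pmin(available, .Machine$integer.max)), n))
  }
  setNames(as.integer(alloc), names(mouse_totals))
}

#' Build per-mouse allocations for every quota in a plan
#'
#' @param plan a [SamplingPlan-class] with quotas.
#' @param ts the [TumorSet-class] being sampled.
#' @param weight_by `"all"` (default): allocation weights are each mouse's
#'   total tumor count over all sgRNAs; `"sgrna"`: weights are the mouse's
#'   tumors of the sgRNA being allocated.
#' @return the plan with its `allocations` slot filled.
#' @export
allocatePlan <- function(plan, ts, weight_by = c("all", "sgrna")) {
  weight_by <- match.arg(weight_by)
  tu <- tumors(ts)
  sa <- sampleInfo(ts)
  q <- quotas(plan)
  rows <- vector("list", nrow(q))
  for (i in seq_len(nrow(q))) {
    mice <- sa$sample[sa$cohort == q$cohort[i]]
    if (!length(mice)) next
    avail <- vapply(mice, function(m)
      sum(tu$sample == m & tu$sgID == q$sgID[i]), integer(1))
    totals <- if (weight_by == "all") {
      vapply(mice, function(m) sum(tu$sample == m), integer(1))
    } else avail
    if (all(totals == 0)) next
    alloc <- allocateAcrossMice(q$n[i], setNames(as.numeric(totals), mice),
                                setNames(avail, mice))
    rows[[i]] <- data.frame(cohort = q$cohort[i], sgID = q$sgID[i],
                            sample = mice, n = alloc, row.names = NULL)
  }
  plan@allocations <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(plan@allocations) <- NULL
  validObject(plan)
  plan
}

#' Select the largest tumors per mouse and sgRNA according to a plan
#'
#' Within each (mouse, sgRNA), keeps the allocation-many largest tumors by
#' cell number, with a deterministic tie-break (reads descending, then
#' lexicographically smaller barcode).
#'
#' @param ts a calibrated [TumorSet-class].
#' @param plan an allocated [SamplingPlan-class] (see [allocatePlan()]); if
#'   quotas exist but allocations are empty, allocation is performed first.
#' @param weight_by passed to [allocatePlan()] when allocation is needed.
#' @return the adaptively sampled [TumorSet-class].
#' @export
sampleTopTumors <- function(ts, plan, weight_by = "all") {
  if (!nrow(allocations(plan)))
    plan <- allocatePlan(plan, ts, weight_by = weight_by)
  tu <- tumors(ts)
  al <- allocations(plan)
  dt <- data.table::as.data.table(tu)
  dt$..row <- seq_len(nrow(tu))
  key <- paste(al$sample, al$sgID)
  dt$..quota <- al$n[match(paste(dt$sample, dt$sgID), key)]
  dt$..quota[is.na(dt$..quota)] <- 0L
  data.table::setorder(dt, sample, sgID, -cells, -reads, barcode)
  dt[, `:=`("..rank", seq_len(.N)), by = c("sample", "sgID")]
  keep <- sort(dt$..row[dt$..rank <= dt$..quota])
  subsetTumors(ts, which = keep)
}

#' Benchmark tumor count for a sampling plan
#'
#' Counts the benchmark vector's tumors supported by at least
#' `min_reads` reads in the benchmark cohort and rounds to the nearest
#' `round_to` (100 at full scale; smaller for desk-scale cohorts). The
#' result seeds [computeSamplingPlan()] and can be overridden for
#' sensitivity analyses.
#'
#' @param ts a [TumorSet-class].
#' @param sgid,cohort benchmark vector and cohort.
#' @param min_reads minimum supporting reads (default 5).
#' @param round_to rounding granularity (default 100).
#' @return integer benchmark N.
#' @export
benchmarkN <- function(ts, sgid, cohort, min_reads = 5L, round_to = 100L) {
  tu <- tumors(ts)
  sa <- sampleInfo(ts)
  mice <- sa$sample[sa$cohort == cohort]
  n <- sum(tu$sgID == sgid & tu$sample %in% mice & tu$reads >= min_reads)
  as.integer(round(n / round_to) * round_to)
}
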