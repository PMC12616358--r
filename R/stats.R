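#' Log-normal maximum-likelihood mean of clone sizes
#'
#' `exp(m + s^2 / 2)` where `m` and `s^2` are the mean and the
#' maximum-likelihood (1/n) variance of log sizes. The best parametric
#' summary of tumor size; because it is computed on adaptively sampled
#' (titer-matched) tumor sets, it integrates effects on both initiation and
#' growth.
#'
#' @param sizes positive cell numbers (n >= 1).
#' @return the LN mean.
#' @export
lnMean <- function(sizes) {
  if (!length(sizes)) .stopData("lnMean needs at least one size")
  if (any(sizes <= 0)) .stopData("sizes must be positive")
  lx <- log(sizes)
  m <- mean(lx)
  s2 <- mean((lx - m)^2)  # 1/n MLE variance
  exp(m + s2 / 2)
}

#' Percentile of a size distribution
#'
#' Order statistic with linear interpolation between closest ranks
#' (`stats::quantile` type 7); the convention is configurable.
#'
#' @param sizes positive cell numbers.
#' @param q percentile in (0, 100).
#' @param type interpolation convention (see [stats::quantile()]).
#' @return the size at the requested percentile.
#' @export
percentileSize <- function(sizes, q, type = 7) {
  if (!length(sizes)) .stopData("percentileSize needs at least one size")
  unname(quantile(sizes, q / 100, type = type))
}

#' Relative statistic against the inert baseline
#'
#' Divides a vector's statistic by the median of the per-inert-vector
#' statistics.
#'
#' @param x_stat statistic for the sgRNA/gene of interest.
#' @param inert_stats per-inert-vector statistics (length >= 1).
#' @return the ratio.
#' @export
relativeMetric <- function(x_stat, inert_stats) {
  if (!length(inert_stats)) .stopData("at least one inert vector required")
  base <- median(inert_stats)
  if (!is.finite(base) || base == 0)
    .stopData("inert baseline statistic is zero or undefined")
  x_stat / base
}

#' Aggregate per-sgRNA statistics to the gene level
#'
#' Weighted average with weights proportional to the number of adaptively
#' sampled tumors per sgRNA.
#'
#' @param stats per-sgRNA statistics.
#' @param counts adaptively sampled tumor counts per sgRNA.
#' @return the gene-level statistic.
#' @export
aggregateGene <- function(stats, counts) {
  stopifnot(length(stats) == length(counts), length(stats) >= 1L)
  ok <- is.finite(stats) & counts > 0
  if (!any(ok)) return(NA_real_)
  sum(stats[ok] * counts[ok]) / sum(counts[ok])
}

#' Benjamini-Hochberg FDR adjustment
#'
#' @param p p-values in `[0, 1]`.
#' @return step-up adjusted q-values (monotone, capped at 1).
#' @export
bhFdr <- function(p) p.adjust(p, method = "BH")

#' Per-mouse tumor number and burden above a size cutoff
#'
#' Tumor number is the count of clonal expansions strictly larger than the
#' cutoff; burden is the total neoplastic cells in those expansions. With
#' `titer_adjust`, both are divided by the mouse's delivered infectious
#' units.
#'
#' @param ts a calibrated [TumorSet-class].
#' @param cutoff cell cutoff (default 500; strict `>`).
#' @param titer_adjust divide by per-mouse titer (default TRUE).
#' @return data.frame: `sample`, `cohort`, `tumor_number`, `burden`.
#' @export
burdenAndNumber <- function(ts, cutoff = 500, titer_adjust = TRUE) {
  tu <- tumors(ts)
  sa <- sampleInfo(ts)
  out <- do.call(rbind, lapply(seq_len(nrow(sa)), function(i) {
    x <- tu[tu$sample == sa$sample[i] & tu$cells > cutoff, , drop = FALSE]
    adj <- if (titer_adjust) sa$titer[i] else 1
    data.frame(sample = sa$sample[i], cohort = sa$cohort[i],
               tumor_number = nrow(x) / adj, burden = sum(x$cells) / adj)
  }))
  rownames(out) <- NULL
  out
}

#' Per-gene relative size statistics on an adaptively sampled cohort
#'
#' Applies the sampling plan to one cohort, computes the per-sgRNA summary
#' statistic (LN mean or percentile size) on the sampled tumors, normalizes
#' by the median across inert vectors, and aggregates sgRNAs to genes
#' weighted by sampled tumor counts.
#'
#' @param ts a calibrated [TumorSet-class] (may contain several cohorts).
#' @param plan a [SamplingPlan-class].
#' @param vectors a [VectorSet-class] (supplies sgRNA -> gene and classes).
#' @param cohort the cohort to evaluate.
#' @param metric `"lnmean"` or `"percentile"`.
#' @param q percentile when `metric = "percentile"`.
#' @param weight_by allocation weight rule (see [allocatePlan()]).
#' @return data.frame `gene`, `estimate`, `n_tumors`, with the per-sgRNA
#'   table in `attr(, "sgrna")`.
#' @export
relativeStats <- function(ts, plan, vectors, cohort,
                          metric = c("lnmean", "percentile"), q = 50,
                          weight_by = "all") {
  metric <- match.arg(metric)
  info <- vectorInfo(vectors)
  sa <- sampleInfo(ts)
  tsc <- subsetTumors(ts, samples = sa$sample[sa$cohort == cohort])
  pl <- plan
  pl@quotas <- quotas(plan)[quotas(plan)$cohort == cohort, , drop = FALSE]
  pl@allocations <- pl@allocations[0, , drop = FALSE]
  sampled <- sampleTopTumors(tsc, pl, weight_by = weight_by)
  tu <- tumors(sampled)
  sgs <- intersect(info$sgID[info$class != "spike_in"], unique(tu$sgID))
  stat <- vapply(sgs, function(g) {
    x <- tu$cells[tu$sgID == g]
    if (!length(x)) return(NA_real_)
    if (metric == "lnmean") lnMean(x) else percentileSize(x, q)
  }, numeric(1))
  nsel <- vapply(sgs, function(g) sum(tu$sgID == g), integer(1))
  cls <- info$class[match(sgs, info$sgID)]
  inert <- stat[cls == "inert" & is.finite(stat)]
  ratio <- relativeMetric(stat, inert)
  per_sg <- data.frame(sgID = sgs, sgRNA = info$sgRNA[match(sgs, info$sgID)],
                       gene = info$gene[match(sgs, info$sgID)], class = cls,
                       stat = stat, ratio = ratio, n_tumors = nsel,
                       row.names = NULL)
  genes <- unique(per_sg$gene)
  out <- do.call(rbind, lapply(genes, function(gn) {
    sub <- per_sg[per_sg$gene == gn, , drop = FALSE]
    data.frame(gene = gn,
               estimate = aggregateGene(sub$ratio, sub$n_tumors),
               n_tumors = sum(sub$n_tumors), row.names = NULL)
  }))
  attr(out, "sgrna") <- per_sg
  out
}

#' BootstrapResult: replicate statistics from a nested bootstrap
#'
#' @slot replicates B x k matrix of replicate statistics (columns named by
#'   unit).
#' @slot point named point estimates on the original data.
#' @slot baseline null-hypothesis value of the statistic (1 for ratios,
#'   0 for differences).
#' @slot B number of replicates.
#' @slot seed RNG seed used.
#' @export
setClass("BootstrapResult", representation(
  replicates = "matrix", point = "numeric", baseline = "numeric",
  B = "integer", seed = "integer"
))

#' @rdname accessors
#' @export
setGeneric("replicates", function(x) standardGeneric("replicates"))
#' @rdname accessors
#' @export
setMethod("replicates", "BootstrapResult", function(x) x@replicates)

setMethod("show", "BootstrapResult", function(object) {
  cat(sprintf("BootstrapResult: %d replicates of %d statistic(s), baseline %g\n",
              object@B, ncol(object@replicates), object@baseline))
})

# Empirical two-sided p: strict inequalities, ties at baseline split
# equally, floored at 2/B so no zero p-values are reported.
.empiricalP <- function(t_rep, baseline, B = length(t_rep)) {
  t_rep <- t_rep[is.finite(t_rep)]
  if (!length(t_rep)) return(NA_real_)
  n <- length(t_rep)
  hi <- (sum(t_rep > baseline) + 0.5 * sum(t_rep == baseline)) / n
  lo <- (sum(t_rep < baseline) + 0.5 * sum(t_rep == baseline)) / n
  min(max(2 * min(hi, lo), 2 / B), 1)
}

#' Summarize a BootstrapResult into an effect table
#'
#' 95% confidence intervals from the 2.5th and 97.5th percentiles of the
#' replicate statistics; two-sided empirical p-values against the baseline;
#' BH-adjusted q-values across units.
#'
#' @param br a [BootstrapResult-class].
#' @param conf confidence level (default 0.95).
#' @return data.frame `unit`, `estimate`, `ci_lo`, `ci_hi`, `p`, `q`.
#' @export
effectTable <- function(br, conf = 0.95) {
  rep <- replicates(br)
  a <- (1 - conf) / 2
  units <- colnames(rep)
  bad <- colMeans(!is.finite(rep))
  if (any(bad > 0.5))
    .stopData("statistic undefined on more than half of the replicates for ",
              paste(units[bad > 0.5], collapse = ", "))
  out <- do.call(rbind, lapply(seq_along(units), function(j) {
    t_rep <- rep[, j]
    fin <- t_rep[is.finite(t_rep)]
    data.frame(unit = units[j], estimate = br@point[j],
               ci_lo = unname(quantile(fin, a)),
               ci_hi = unname(quantile(fin, 1 - a)),
               p = .empiricalP(t_rep, br@baseline, br@B), row.names = NULL)
  }))
  out$q <- bhFdr(out$p)
  out
}

#' Nested hierarchical bootstrap of an arbitrary statistic
#'
#' Two-step resampling that propagates both mouse-to-mouse variability and
#' within-mouse tumor sampling: mice are resampled with replacement to the
#' original cohort size (stratified by cohort when several are present),
#' then tumors are resampled with replacement within each selected mouse to
#' that mouse's tumor count. The statistic is re-evaluated on each
#' pseudo-dataset -- including any adaptive sampling it performs internally.
#'
#' @param ts a [TumorSet-class].
#' @param statistic function taking a [TumorSet-class] and returning a named
#'   numeric vector.
#' @param B number of replicates (default 10000).
#' @param seed RNG seed.
#' @param baseline null value of the statistic (default 1 for ratios).
#' @return a [BootstrapResult-class].
#' @export
nestedBootstrap <- function(ts, statistic, B = 10000L, seed = 1L,
                            baseline = 1) {
  sa <- sampleInfo(ts)
  tu <- tumors(ts)
  if (nrow(sa) < 2L) .stopData("nested bootstrap needs at least 2 mice")
  point <- statistic(ts)
  set.seed(seed)
  idx_by_mouse <- split(seq_len(nrow(tu)), factor(tu$sample, sa$sample))
  cohorts <- split(seq_len(nrow(sa)), sa$cohort)
  rep <- matrix(NA_real_, B, length(point),
                dimnames = list(NULL, names(point)))
  for (b in seq_len(B)) {
    rows <- unlist(lapply(cohorts, function(ci) {
      ms <- ci[sample.int(length(ci), length(ci), replace = TRUE)]
      unlist(lapply(ms, function(m) {
        ix <- idx_by_mouse[[m]]
        if (!length(ix)) return(integer(0))
        ix[sample.int(length(ix), length(ix), replace = TRUE)]
      }), use.names = FALSE)
    }), use.names = FALSE)
    # pseudo-mice keep their original ids: a mouse drawn twice contributes
    # two resamples pooled under its id (allocation still follows totals)
    pseudo <- tu[rows, , drop = FALSE]
    ps <- new("TumorSet", tumors = pseudo, samples = sa)
    val <- tryCatch(statistic(ps), error = function(e) NULL)
    if (!is.null(val)) rep[b, ] <- val[names(point)]
  }
  new("BootstrapResult", replicates = rep, point = point,
      baseline = baseline, B = as.integer(B), seed = as.integer(seed))
}

#' Fast nested bootstrap of the per-gene relative LN mean
#'
#' Compiled implementation of [nestedBootstrap()] specialized to the
#' per-gene relative LN mean of [relativeStats()]: mice resampled with
#' replacement, tumors resampled within mice, adaptive sampling re-executed
#' per pseudo-dataset. The point estimate equals `relativeStats()` exactly.
#'
#' @param ts a calibrated [TumorSet-class].
#' @param plan a [SamplingPlan-class] with quotas for `cohort`.
#' @param vectors a [VectorSet-class].
#' @param cohort cohort to bootstrap.
#' @param B replicates (default 10000).
#' @param seed RNG seed.
#' @return a [BootstrapResult-class] with one column per gene.
#' @export
bootstrapRelativeLNMean <- function(ts, plan, vectors, cohort, B = 10000L,
                                    seed = 1L) {
  prep <- .prepKernel(ts, plan, vectors, cohort)
  point_tab <- relativeStats(ts, plan, vectors, cohort, metric = "lnmean")
  point <- setNames(point_tab$estimate, point_tab$gene)[prep$genes]
  set.seed(seed)
  rep <- cq_boot_rel_lnmean(prep$logc, prep$mouse_of, prep$sg_of,
                            prep$n_mice, prep$n_sg, prep$quota,
                            prep$inert, prep$gene_of_sg,
                            length(prep$genes), as.integer(B))
  colnames(rep) <- prep$genes
  new("BootstrapResult", replicates = rep, point = point,
      baseline = 1, B = as.integer(B), seed = as.integer(seed))
}

# Lay the cohort's tumors out for the compiled kernel: rows sorted
# mouse-major, then sgRNA, then cells descending (reads desc / barcode asc
# tie-break), with 0-based group labels.
.prepKernel <- function(ts, plan, vectors, cohort) {
  info <- vectorInfo(vectors)
  sa <- sampleInfo(ts)
  mice <- sa$sample[sa$cohort == cohort]
  if (length(mice) < 2L) .stopData("nested bootstrap needs at least 2 mice")
  tu <- tumors(ts)
  tu <- tu[tu$sample %in% mice, , drop = FALSE]
  q <- quotas(plan)
  q <- q[q$cohort == cohort, , drop = FALSE]
  sgs <- intersect(info$sgID[info$class != "spike_in"], unique(tu$sgID))
  tu <- tu[tu$sgID %in% sgs, , drop = FALSE]
  dt <- data.table::as.data.table(tu)
  dt$..m <- match(dt$sample, mice) - 1L
  dt$..v <- match(dt$sgID, sgs) - 1L
  data.table::setorder(dt, ..m, ..v, -cells, -reads, barcode)
  quota <- q$n[match(sgs, q$sgID)]
  quota[is.na(quota)] <- 0L
  genes <- unique(info$gene[match(sgs, info$sgID)])
  list(logc = log(dt$cells), mouse_of = dt$..m, sg_of = dt$..v,
       n_mice = length(mice), n_sg = length(sgs),
       quota = as.integer(quota),
       inert = info$class[match(sgs, info$sgID)] == "inert",
       gene_of_sg = match(info$gene[match(sgs, info$sgID)], genes) - 1L,
       genes = genes)
}

#' Young-versus-aged contrast of bootstrapped effects
#'
#' Pairs replicate-wise independent bootstrap distributions from the two
#' cohorts and forms `T = effect_young - effect_aged`. Under the null of
#' equal effect, T = 0; two-sided p-values use the empirical tail
#' proportions and are BH-adjusted across genes.
#'
#' @param young,aged [BootstrapResult-class] objects over the same units.
#' @return data.frame `unit`, `estimate` (difference), `ci_lo`, `ci_hi`,
#'   `p`, `q`.
#' @export
contrastAge <- function(young, aged) {
  units <- intersect(colnames(replicates(young)), colnames(replicates(aged)))
  if (!length(units)) .stopData("no shared units between cohorts")
  B <- min(nrow(replicates(young)), nrow(replicates(aged)))
  t_rep <- replicates(young)[seq_len(B), units, drop = FALSE] -
    replicates(aged)[seq_len(B), units, drop = FALSE]
  br <- new("BootstrapResult", replicates = t_rep,
            point = young@point[units] - aged@point[units],
            baseline = 0, B = B, seed = young@seed)
  effectTable(br)
}

#' Fit the reduction factor R matching young and aged inert tumor counts
#'
#' R is the proportional reduction in tumor size that, applied to the young
#' mice, minimizes the absolute difference between the median per-mouse
#' count of inert tumors above cutoff in young and aged mice: reduced young
#' sizes `R x size` are compared against the aged cutoff `L`, equivalently
#' original young sizes against the adjusted cutoff `L / R`. A shrink of
#' aged tumors to half size therefore fits R near 0.5.
#'
#' The young count is monotone non-decreasing in R, so the objective is
#' piecewise constant with a single minimizing plateau; the default search
#' bisects the monotone count difference to the crossing, then resolves the
#' plateau tie toward R = 1 (no reduction). A grid search (step 0.01) is
#' available as an oracle.
#'
#' @param young,aged calibrated [TumorSet-class] objects.
#' @param vectors a [VectorSet-class] (identifies inert vectors).
#' @param L aged-cohort cell cutoff (default 500).
#' @param method `"bisect"` (default) or `"grid"`.
#' @param interval search range for R.
#' @param grid_step grid resolution for `method = "grid"`.
#' @return the fitted R.
#' @export
fitReductionFactor <- function(young, aged, vectors, L = 500,
                               method = c("bisect", "grid"),
                               interval = c(0.01, 2), grid_step = 0.01) {
  method <- match.arg(method)
  info <- vectorInfo(vectors)
  inert_sg <- info$sgID[info$class == "inert"]
  countMedian <- function(ts, cutoff) {
    tu <- tumors(ts)
    sa <- sampleInfo(ts)
    median(vapply(sa$sample, function(s)
      sum(tu$sample == s & tu$sgID %in% inert_sg & tu$cells > cutoff),
      numeric(1)))
  }
  target <- countMedian(aged, L)
  gap <- function(r) countMedian(young, L / r) - target  # non-decreasing
  obj <- function(r) abs(gap(r))
  if (method == "grid") {
    rs <- seq(interval[1], interval[2], by = grid_step)
    vals <- vapply(rs, obj, numeric(1))
    cand <- rs[vals == min(vals)]
    return(cand[which.min(abs(cand - 1))])
  }
  lo <- interval[1]; hi <- interval[2]
  glo <- gap(lo); ghi <- gap(hi)
  r0 <- if (glo >= 0) {
    lo                      # counts too high everywhere: left end is closest
  } else if (ghi <= 0) {
    hi                      # counts too low everywhere: right end is closest
  } else {
    for (it in seq_len(50)) {     # keep gap(lo) < 0 <= gap(hi)
      mid <- (lo + hi) / 2
      if (gap(mid) < 0) lo <- mid else hi <- mid
    }
    if (abs(gap(lo)) != abs(gap(hi))) {
      if (abs(gap(lo)) < abs(gap(hi))) lo else hi
    } else {
      c(lo, hi)[which.min(abs(c(lo, hi) - 1))]
    }
  }
  f0 <- obj(r0)
  # walk the minimizing plateau toward R = 1 by bisection on equality
  edge <- if (r0 <= 1) min(1, interval[2]) else max(1, interval[1])
  if (obj(edge) == f0) return(edge)
  a <- r0; b <- edge
  for (it in seq_len(50)) {
    mid <- (a + b) / 2
    if (obj(mid) == f0) a <- mid else b <- mid
  }
  a
}

#' scoreRGM: ratio-of-geometric-means contrast between cohorts
#'
#' Compares the effect of inactivating gene X between aged and young
#' cohorts on matched portions of the tumor size distribution. With `N_L`
#' the number of inert tumors above `L` in aged mice, `N_{LxR}` the
#' equivalent number in young mice (above the adjusted cutoff `L / R`), and
#' `p_X` the ratio of sgX to inert tumor
#' counts (computed within each cohort above its cutoff), the score is
#'
#' `log2( (GM[top p_X * N_L sgX aged] / GM[top N_L inert aged]) /
#'        (GM[top p_X * N_{LxR} sgX young] / GM[top N_{LxR} inert young]) )`
#'
#' Zero under young/aged exchangeability; positive when X suppresses tumors
#' more strongly in aged mice, negative when more strongly in young mice.
#'
#' @param young,aged calibrated [TumorSet-class] objects.
#' @param vectors a [VectorSet-class].
#' @param gene the target gene X.
#' @param L aged-cohort cell cutoff (default 500).
#' @param R reduction factor; fitted via [fitReductionFactor()] when NULL.
#' @return list with `score`, `R`, `N_L`, `N_LR`, `p_young`, `p_aged`.
#' @export
scoreRGM <- function(young, aged, vectors, gene, L = 500, R = NULL) {
  info <- vectorInfo(vectors)
  inert_sg <- info$sgID[info$class == "inert"]
  x_sg <- info$sgID[info$gene == gene & info$class != "spike_in"]
  if (!length(x_sg)) .stopData("no vectors target gene ", gene)
  if (is.null(R)) R <- fitReductionFactor(young, aged, vectors, L = L)
  sizesAbove <- function(ts, sgs, cutoff) {
    tu <- tumors(ts)
    sort(tu$cells[tu$sgID %in% sgs & tu$cells > cutoff], decreasing = TRUE)
  }
  gmTop <- function(sizes, k) {
    k <- max(1L, as.integer(round(k)))
    if (!length(sizes))
      .stopData("empty tumor set for geometric mean (k = ", k, ")")
    exp(mean(log(sizes[seq_len(min(k, length(sizes)))])))
  }
  inert_aged <- sizesAbove(aged, inert_sg, L)
  inert_young <- sizesAbove(young, inert_sg, L / R)
  if (!length(inert_aged) || !length(inert_young))
    .stopData("no inert tumors above cutoff (aged: ", length(inert_aged),
              ", young: ", length(inert_young), ")")
  n_l <- length(inert_aged)
  n_lr <- length(inert_young)
  x_aged <- sizesAbove(aged, x_sg, L)
  x_young <- sizesAbove(young, x_sg, L / R)
  p_aged <- length(x_aged) / n_l
  p_young <- length(x_young) / n_lr
  num <- gmTop(x_aged, p_aged * n_l) / gmTop(inert_aged, n_l)
  den <- gmTop(x_young, p_young * n_lr) / gmTop(inert_young, n_lr)
  list(score = log2(num / den), R = R, N_L = n_l, N_LR = n_lr,
       p_young = p_young, p_aged = p_aged)
}

#' Titer-scaled comparison of tumor size distributions
#'
#' Selects the `n_young` largest tumors from each young sample and
#' `round(n_young * titer_ratio)` largest from each aged sample (so both
#' cohorts contribute the same number of tumors per infectious unit), pools
#' them, and compares the empirical CDFs with the two-sided asymptotic
#' Kolmogorov-Smirnov test.
#'
#' @param young,aged named lists of per-sample size vectors.
#' @param n_young tumors selected per young sample.
#' @param titer_ratio aged-to-young titer ratio.
#' @return list with `young_selected`, `aged_selected` (per-sample lists),
#'   `n_aged`, `D`, `p`.
#' @export
ecdfCompare <- function(young, aged, n_young, titer_ratio) {
  n_aged <- as.integer(round(n_young * titer_ratio))
  selectTop <- function(sizes, n) {
    if (length(sizes) < n)
      warning(sprintf("sample has %d tumors, fewer than the requested %d",
                      length(sizes), n))
    sort(sizes, decreasing = TRUE)[seq_len(min(n, length(sizes)))]
  }
  ys <- lapply(young, selectTop, n = n_young)
  as <- lapply(aged, selectTop, n = n_aged)
  ks <- suppressWarnings(
    ks.test(unlist(ys), unlist(as), alternative = "two.sided", exact = FALSE))
  list(young_selected = ys, aged_selected = as, n_aged = n_aged,
       D = unname(ks$statistic), p = ks$p.value)
}
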