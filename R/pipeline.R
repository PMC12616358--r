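#' Read / write tumor and vector tables as TSV
#'
#' Plain tab-separated interchange formats: the tumor table carries
#' `sample`, `sgID`, `barcode`, `reads`, `cells` plus the sample metadata
#' columns on a side table; the vector table carries `sgID`, `sgRNA`,
#' `gene`, `class` and optional `p`.
#'
#' @param path file path.
#' @name tsv-io
NULL

#' @rdname tsv-io
#' @export
readVectorTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sgID", "sgRNA", "gene", "class")
  if (!all(need %in% names(df)))
    .stopData("vector table ", path, " must have columns ",
              paste(need, collapse = ", "))
  df
}

#' @rdname tsv-io
#' @param ts a [TumorSet-class].
#' @export
writeTumorTable <- function(ts, path) {
  write.table(tumors(ts), path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta_path <- sub("(\\.tsv)?$", ".samples.tsv", path)
  write.table(sampleInfo(ts), meta_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(path, meta_path))
}

#' @rdname tsv-io
#' @export
readTumorTable <- function(path) {
  tu <- read.delim(path, stringsAsFactors = FALSE)
  sa <- read.delim(sub("(\\.tsv)?$", ".samples.tsv", path),
                   stringsAsFactors = FALSE)
  TumorSet(tu, sa)
}

#' Default pipeline options for the desk-scale demo configuration
#'
#' QC thresholds are scaled to the synthetic cohort size (about 100x
#' smaller than real mice) in the same 4:12:3 proportion as the full-scale
#' defaults; the benchmark vector is the first inert vector in the young
#' cohort.
#'
#' @param B bootstrap replicates for the stats stage.
#' @return named list of options for [runPipeline()].
#' @export
demoPipelineOptions <- function(B = 1000L) {
  list(thresholds = qcThresholds(100L, 300L, 75L, 5L),
       benchmark_sgrna = "sgNT1",
       benchmark_cohort = "young",
       n_benchmark = NULL,       # auto via benchmarkN()
       rescue_share = 0.95,
       recurrence_quantile = 0.999,
       benchmark_round = 10L,
       B = as.integer(B))
}

#' Run the full pipeline on a truth configuration
#'
#' simulate -> render -> process -> contamination filter -> QC -> adaptive
#' sampling -> effect statistics, with per-stage seeds derived from the root
#' seed, intermediate tables optionally persisted as TSV, and a manifest
#' reconciling record counts across stages. Reruns with the same config and
#' seed reproduce identical outputs.
#'
#' @param config a `truth_config` (see [truthConfig()], [demoConfig()]).
#' @param opts options list (see [demoPipelineOptions()]).
#' @param seed root RNG seed.
#' @param out_dir optional directory for stage TSVs and `manifest.json`.
#' @return list with `truth`, `tumors` (processed), `filtered`, `qc_passed`,
#'   `plan`, `sampled`, `effects` (per cohort), `contrast` (when two
#'   Cas9-positive cohorts are present), `manifest`.
#' @export
runPipeline <- function(config, opts = demoPipelineOptions(), seed = 1L,
                        out_dir = NULL) {
  validateTruthConfig(config)
  manifest <- list(seed = seed, stages = list())
  note <- function(stage, n_in, n_out, removed = n_in - n_out) {
    manifest$stages[[stage]] <<- list(n_in = n_in, n_out = n_out,
                                      removed = removed)
  }

  # simulate + render
  truth <- simulateTruth(config, seed = seed)
  counts <- renderReads(truth, seed = seed)
  note("simulate", 0L, nrow(truth@truth), 0L)
  note("render", nrow(truth@truth), nrow(counts), NA)

  vectors <- VectorSet(config$vectors[c("sgID", "sgRNA", "gene", "class")])
  spike <- truth@pool$spike

  # process
  proc <- processCounts(counts, vectors, spike, truth@samples)
  note("process", nrow(counts), nrow(tumors(proc$tumors)))

  # contamination filter
  model <- fitContaminationModels(proc$tumors,
                                  quantile = opts$recurrence_quantile)
  filt <- applyRecurrenceFilter(proc$tumors, model,
                                rescue_share = opts$rescue_share)
  note("filter", nrow(tumors(proc$tumors)), nrow(tumors(filt$tumors)))

  # QC: mice then vectors; Cas9-negative cohorts corroborate vector filter
  sa <- sampleInfo(filt$tumors)
  cas9_neg <- sa$sample[!sa$cas9]
  experimental <- subsetTumors(filt$tumors, samples = setdiff(sa$sample,
                                                              cas9_neg))
  control <- if (length(cas9_neg))
    subsetTumors(filt$tumors, samples = cas9_neg) else NULL
  qc_res <- applyQcFilters(experimental, control = control,
                           thresholds = opts$thresholds)
  qc_passed <- qc_res$tumors
  note("qc", nrow(tumors(filt$tumors)), nrow(tumors(qc_passed)))

  # pool proportions: Cas9-negative control when available, else configured
  retained_sg <- unique(tumors(qc_passed)$sgID)
  props <- if (!is.null(control)) {
    estimatePoolProportions(control, sgids = retained_sg)
  } else {
    p <- config$vectors$p[match(retained_sg, config$vectors$sgID)]
    data.frame(sgID = retained_sg, p = p / sum(p))
  }

  # adaptive sampling
  qsa <- sampleInfo(qc_passed)
  cohort_tab <- do.call(rbind, lapply(unique(qsa$cohort), function(co)
    data.frame(cohort = co, titer_total = sum(qsa$titer[qsa$cohort == co]))))
  n_bench <- opts$n_benchmark
  bench_sgid <- vectorInfo(vectors)$sgID[
    vectorInfo(vectors)$sgRNA == opts$benchmark_sgrna]
  if (is.null(n_bench))
    n_bench <- benchmarkN(qc_passed, bench_sgid, opts$benchmark_cohort,
                          min_reads = opts$thresholds$min_reads_support,
                          round_to = if (is.null(opts$benchmark_round)) 100L
                                     else opts$benchmark_round)
  plan <- computeSamplingPlan(bench_sgid, opts$benchmark_cohort, n_bench,
                              cohort_tab, props)
  sampled <- sampleTopTumors(qc_passed, plan)
  note("sample", nrow(tumors(qc_passed)), nrow(tumors(sampled)))

  # effect statistics per cohort + young/aged contrast
  cohorts <- unique(qsa$cohort)
  boots <- list()
  effects <- list()
  for (i in seq_along(cohorts)) {
    br <- bootstrapRelativeLNMean(qc_passed, plan, vectors, cohorts[i],
                                  B = opts$B,
                                  seed = .stageSeed(seed, 10L + i))
    boots[[cohorts[i]]] <- br
    effects[[cohorts[i]]] <- effectTable(br)
  }
  contrast <- NULL
  if (length(cohorts) == 2L)
    contrast <- contrastAge(boots[[1L]], boots[[2L]])
  note("stats", nrow(tumors(sampled)),
       sum(vapply(effects, nrow, integer(1))), 0L)

  out <- list(truth = truth, tumors = proc$tumors, filtered = filt$tumors,
              qc_passed = qc_passed, plan = plan, sampled = sampled,
              effects = effects, contrast = contrast,
              model = model, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writeTumorTable(proc$tumors, file.path(out_dir, "tumors.tsv"))
    writeTumorTable(qc_passed, file.path(out_dir, "qc_passed.tsv"))
    writeTumorTable(sampled, file.path(out_dir, "sampled.tsv"))
    write.table(quotas(plan), file.path(out_dir, "plan.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    for (co in names(effects))
      write.table(effects[[co]],
                  file.path(out_dir, paste0("effects_", co, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(contrast))
      write.table(contrast, file.path(out_dir, "contrast.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}
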