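#' Build a truth configuration for synthetic Tuba-seq cohorts
#'
#' The configuration fully specifies the generative model the downstream
#' pipeline assumes: a lentiviral pool with finite per-vector barcode
#' diversity, per-mouse Poisson tumor numbers scaled by titer and pool
#' proportion, log-normal clone sizes with per-gene/per-age multiplicative
#' effects, three 1e5-cell spike-in lines, and a read-rendering noise channel
#' (per-base substitution errors plus cross-sample contamination).
#'
#' @param vectors data.frame with columns `sgID`, `sgRNA`, `gene`, `class`,
#'   `p` (pool proportion; must sum to 1 over non-spike vectors).
#' @param cohorts data.frame with columns `cohort`, `age_group`, `n_mice`,
#'   `titer_per_mouse` (infectious units), `initiation_multiplier`
#'   (dimensionless age effect on tumors per infectious unit), and logical
#'   `cas9` (FALSE marks Cas9-negative control cohorts in which all vectors
#'   are functionally inert).
#' @param barcode_diversity distinct 20-mers available per vector (emulates
#'   the number of bacterial colonies pooled when barcoding the plasmid).
#' @param initiation_rate tumors per infectious unit in the reference
#'   (young) condition.
#' @param size_meanlog named numeric: baseline log-scale location of clone
#'   sizes per age group.
#' @param size_sdlog log-scale standard deviation of clone sizes (> 0).
#' @param effect_multipliers data.frame with columns `gene`, `age_group`,
#'   `multiplier`: multiplicative effect of gene inactivation on clone size
#'   (natural scale). Genes/ages absent default to 1. Ignored in Cas9-negative
#'   cohorts.
#' @param read_depth expected total reads per sample.
#' @param substitution_error_rate per-base substitution probability in the
#'   rendered cassette.
#' @param cross_contamination_fraction probability that a read is re-labeled
#'   to another sample.
#' @param contamination_mode `"uniform"` (any read may hop, destination
#'   uniform over other samples) or `"dominant"` (all contaminating reads
#'   originate from the single largest clone, emulating index hopping from
#'   one very large tumor).
#' @param read_mode `"poisson"` (independent Poisson reads per clone),
#'   `"multinomial"` (exact multinomial at the configured depth), or
#'   `"expected"` (deterministic expected counts; exact round-trips).
#' @param tumor_number_law currently `"poisson"`; recorded so the generative
#'   choice for tumor number per mouse is explicit in the config.
#' @param spike_cells cells per spike-in line (3 lines).
#' @return a validated `truth_config` list.
#' @export
truthConfig <- function(vectors,
                        cohorts,
                        barcode_diversity = 5000L,
                        initiation_rate = 0.2,
                        size_meanlog = c(young = log(20), aged = log(10)),
                        size_sdlog = 2,
                        effect_multipliers = NULL,
                        read_depth = 1e6,
                        substitution_error_rate = 0.001,
                        cross_contamination_fraction = 0.002,
                        contamination_mode = c("uniform", "dominant"),
                        read_mode = c("poisson", "multinomial", "expected"),
                        tumor_number_law = "poisson",
                        spike_cells = 1e5) {
  contamination_mode <- match.arg(contamination_mode)
  read_mode <- match.arg(read_mode)
  if (is.null(effect_multipliers))
    effect_multipliers <- data.frame(gene = character(0),
                                     age_group = character(0),
                                     multiplier = numeric(0))
  vectors <- as.data.frame(vectors)
  cohorts <- as.data.frame(cohorts)
  if (!"cas9" %in% names(cohorts)) cohorts$cas9 <- TRUE
  cfg <- structure(list(
    vectors = vectors, cohorts = cohorts,
    barcode_diversity = as.integer(barcode_diversity),
    initiation_rate = initiation_rate,
    size_meanlog = size_meanlog, size_sdlog = size_sdlog,
    effect_multipliers = as.data.frame(effect_multipliers),
    read_depth = read_depth,
    substitution_error_rate = substitution_error_rate,
    cross_contamination_fraction = cross_contamination_fraction,
    contamination_mode = contamination_mode,
    read_mode = read_mode,
    tumor_number_law = tumor_number_law,
    spike_cells = spike_cells,
    n_spike = 3L
  ), class = "truth_config")
  validateTruthConfig(cfg)
  cfg
}

#' Validate a truth configuration
#'
#' @param cfg a `truth_config` list.
#' @return the config, invisibly; raises a configuration error otherwise.
#' @export
validateTruthConfig <- function(cfg) {
  v <- cfg$vectors
  if (!all(c("sgID", "sgRNA", "gene", "class", "p") %in% names(v)))
    .stopConfig("vectors must have columns sgID, sgRNA, gene, class, p")
  coll <- .sgidCollision(v$sgID)
  if (!is.null(coll))
    .stopConfig(sprintf("sgID collision (fewer than 3 mismatches): %s vs %s",
                        coll[1], coll[2]))
  if (abs(sum(v$p) - 1) > 1e-6)
    .stopConfig("pool proportions must sum to 1")
  if (cfg$barcode_diversity < 1L)
    .stopConfig("barcode_diversity must be >= 1")
  if (cfg$size_sdlog < 0) .stopConfig("size_sdlog must be >= 0")
  probs <- c(cfg$substitution_error_rate, cfg$cross_contamination_fraction)
  if (any(probs < 0 | probs > 1))
    .stopConfig("error and contamination rates must lie in [0, 1]")
  co <- cfg$cohorts
  need <- c("cohort", "age_group", "n_mice", "titer_per_mouse",
            "initiation_multiplier")
  if (!all(need %in% names(co)))
    .stopConfig("cohorts must have columns ", paste(need, collapse = ", "))
  if (!all(co$age_group %in% names(cfg$size_meanlog)))
    .stopConfig("every cohort age_group needs an entry in size_meanlog")
  invisible(cfg)
}

# Default 8-vector demo pool. sgIDs are two blocks of four identical
# nucleotides, so any two differ at >= 4 positions.
.demoVectors <- function() {
  data.frame(
    sgID = c("AAAACCCC", "CCCCAAAA", "GGGGTTTT", "TTTTGGGG",
             "AAAAGGGG", "GGGGAAAA", "CCCCTTTT", "TTTTCCCC"),
    sgRNA = c("sgNT1", "sgNT2", "sgNT3", "sgGeneA1",
              "sgGeneA2", "sgGeneB1", "sgGeneC1", "sgGeneD1"),
    gene = c("NT1", "NT2", "NT3", "GeneA",
             "GeneA", "GeneB", "GeneC", "GeneD"),
    class = c("inert", "inert", "inert", rep("targeting", 5)),
    p = rep(1 / 8, 8)
  )
}

.SPIKE_SGID <- "AAAATTTT"
.SPIKE_BC20 <- c("ACGTACGTACGTACGTACGT",
                 "TGCATGCATGCATGCATGCA",
                 "GATCGATCGATCGATCGATC")

#' Demo truth configuration
#'
#' Two cohorts (young, aged) of four mice each, eight vectors (three inert,
#' five targeting across four genes), with the aged cohort receiving a
#' threefold higher titer and a reduced per-infectious-unit initiation rate
#' and baseline clone size, mirroring the design of titer-compensated
#' young/aged tumor-barcoding experiments at desk scale.
#'
#' @param n_mice mice per cohort.
#' @param read_depth expected reads per sample; the demo default gives the
#'   low per-clone coverage regime of real libraries, where small clones
#'   fall below the 5-read benchmark support.
#' @param ... further arguments passed to [truthConfig()].
#' @return a `truth_config`.
#' @export
demoConfig <- function(n_mice = 4L, read_depth = 8e4, ...) {
  cohorts <- data.frame(
    cohort = c("young", "aged"),
    age_group = c("young", "aged"),
    n_mice = as.integer(n_mice),
    titer_per_mouse = c(3000, 9000),
    initiation_multiplier = c(1, 0.6),
    cas9 = TRUE
  )
  truthConfig(vectors = .demoVectors(), cohorts = cohorts,
              read_depth = read_depth, ...)
}

#' Generate the lentiviral pool: finite barcode sets per vector
#'
#' Each vector owns `barcode_diversity` distinct random 20-mers (the
#' degenerate positions of the 30-nt cassette); the three spike-in lines use
#' fixed reserved barcodes outside all vector sets, under their own sgID.
#'
#' @param config a `truth_config`.
#' @param seed RNG seed; identical config + seed gives identical pools.
#' @return list with `vectors` (the vector table), `barcodes` (named list of
#'   20-nt sets per sgID), `spike` (list with `sgID`, `barcodes`,
#'   `cells_per_line`).
#' @export
generatePool <- function(config, seed = 1L) {
  validateTruthConfig(config)
  coll <- .sgidCollision(c(config$vectors$sgID, .SPIKE_SGID))
  if (!is.null(coll))
    .stopConfig(sprintf("sgID collision (fewer than 3 mismatches): %s vs %s",
                        coll[1], coll[2]))
  set.seed(seed)
  reserved <- .SPIKE_BC20
  barcodes <- lapply(seq_len(nrow(config$vectors)), function(i) {
    bc <- .randomBarcodes(config$barcode_diversity + length(reserved), 20L)
    setdiff(bc, reserved)[seq_len(config$barcode_diversity)]
  })
  names(barcodes) <- config$vectors$sgID
  list(vectors = config$vectors,
       barcodes = barcodes,
       spike = list(sgID = .SPIKE_SGID, barcodes = reserved,
                    cells_per_line = config$spike_cells))
}

# Per-gene, per-age clone-size multiplier lookup (1 where unspecified).
.effectMultiplier <- function(config, genes, age_group) {
  em <- config$effect_multipliers
  out <- rep(1, length(genes))
  if (nrow(em)) {
    hit <- match(paste(genes, age_group), paste(em$gene, em$age_group))
    out[!is.na(hit)] <- em$multiplier[hit[!is.na(hit)]]
  }
  out
}

#' Simulate one cohort's tumors from the generative model
#'
#' Per mouse and vector, the tumor count is Poisson with mean
#' titer x pool proportion x initiation rate x cohort initiation multiplier;
#' each tumor's cell number is a rounded log-normal draw (floor 1) whose
#' log-location is the age baseline plus the log of the gene's effect
#' multiplier; barcodes are drawn with replacement from the vector's finite
#' set. Cas9-negative cohorts ignore effect multipliers (all vectors inert).
#'
#' @param config a `truth_config`.
#' @param cohort cohort id (row of `config$cohorts`).
#' @param pool pool from [generatePool()].
#' @return data.frame with one row per simulated tumor: `sample`, `cohort`,
#'   `sgID`, `gene`, `barcode` (30-nt cassette), `cells`.
#' @export
simulateCohort <- function(config, cohort, pool) {
  co <- config$cohorts[config$cohorts$cohort == cohort, , drop = FALSE]
  if (nrow(co) != 1L) .stopConfig("unknown cohort: ", cohort)
  v <- config$vectors
  age <- co$age_group
  cas9 <- if ("cas9" %in% names(co)) isTRUE(co$cas9) else TRUE
  mult <- if (cas9) .effectMultiplier(config, v$gene, age) else rep(1, nrow(v))
  meanlog <- config$size_meanlog[[age]] + log(mult)
  rows <- vector("list", co$n_mice * nrow(v))
  k <- 0L
  for (m in seq_len(co$n_mice)) {
    sample_id <- sprintf("%s_m%02d", cohort, m)
    lam <- co$titer_per_mouse * v$p * config$initiation_rate *
      co$initiation_multiplier
    nt <- rpois(nrow(v), lam)
    for (i in seq_len(nrow(v))) {
      if (nt[i] == 0L) next
      sizes <- pmax(1, round(rlnorm(nt[i], meanlog[i], config$size_sdlog)))
      bcs <- sample(pool$barcodes[[v$sgID[i]]], nt[i], replace = TRUE)
      k <- k + 1L
      rows[[k]] <- data.frame(sample = sample_id, cohort = cohort,
                              sgID = v$sgID[i], gene = v$gene[i],
                              barcode = renderCassette(bcs), cells = sizes)
    }
  }
  out <- if (k) do.call(rbind, rows[seq_len(k)]) else
    data.frame(sample = character(0), cohort = character(0),
               sgID = character(0), gene = character(0),
               barcode = character(0), cells = numeric(0))
  rownames(out) <- NULL
  out
}

#' Simulate all cohorts into a SyntheticTruth
#'
#' @param config a `truth_config`.
#' @param seed RNG seed (drives pool generation and all cohort draws).
#' @return a [SyntheticTruth-class].
#' @export
simulateTruth <- function(config, seed = 1L) {
  pool <- generatePool(config, seed = .stageSeed(seed, 1L))
  set.seed(.stageSeed(seed, 2L))
  truth <- do.call(rbind, lapply(config$cohorts$cohort, function(co)
    simulateCohort(config, co, pool)))
  co <- config$cohorts
  samples <- do.call(rbind, lapply(seq_len(nrow(co)), function(i) {
    data.frame(sample = sprintf("%s_m%02d", co$cohort[i], seq_len(co$n_mice[i])),
               cohort = co$cohort[i], age_group = co$age_group[i],
               titer = co$titer_per_mouse[i],
               cas9 = if ("cas9" %in% names(co)) co$cas9[i] else TRUE)
  }))
  rownames(samples) <- NULL
  new("SyntheticTruth", truth = truth, samples = samples,
      pool = pool, config = unclass(config))
}

#' Aggregate a truth table to unique clones
#'
#' Tumors in the same mouse that drew the same barcode from the finite pool
#' are indistinguishable in sequencing; this sums their cell numbers so truth
#' can be compared record-for-record with pipeline output.
#'
#' @param truth a [SyntheticTruth-class] or its truth data.frame.
#' @return data.frame keyed by (sample, sgID, barcode) with summed `cells`.
#' @export
aggregateTruth <- function(truth) {
  df <- if (is(truth, "SyntheticTruth")) truth@truth else truth
  dt <- data.table::as.data.table(df)
  out <- dt[, list(cells = sum(cells)), by = c("sample", "sgID", "barcode")]
  data.table::setorder(out, sample, sgID, barcode)
  as.data.frame(out)
}

# Mutate k cassette strings: each guaranteed >= 1 substitution, positions
# binomially distributed at the per-base rate (conditioned on >= 1).
.mutateCassettes <- function(bc, rate) {
  k <- length(bc)
  if (k == 0L) return(character(0))
  nmut <- rbinom(k, 30L, rate)
  while (any(nmut == 0L)) {
    z <- nmut == 0L
    nmut[z] <- rbinom(sum(z), 30L, rate)
  }
  vapply(seq_len(k), function(i) {
    s <- strsplit(bc[i], "")[[1]]
    pos <- sample.int(30L, nmut[i])
    for (p in pos) s[p] <- sample(setdiff(.DNA, s[p]), 1L)
    paste(s, collapse = "")
  }, character(1))
}

#' Render per-sample read counts from a synthetic truth
#'
#' Reads per clone follow the configured sampling law around the clone's
#' share of the sequencing depth (total cells include the three spike-in
#' lines); each read is then independently mutated per base at the
#' substitution error rate (creating spurious neighbor barcodes) and
#' re-labeled to another sample with the cross-contamination probability.
#' Spike-in reads are rendered identically from `spike_cells` per line.
#'
#' @param truth a [SyntheticTruth-class].
#' @param seed RNG seed.
#' @param read_mode,error_rate,contamination override the config values.
#' @return data.frame of rendered counts: `sample`, `sgID`, `barcode`,
#'   `reads`. Includes spike-in rows under the spike sgID.
#' @export
renderReads <- function(truth, seed = 1L, read_mode = NULL,
                        error_rate = NULL, contamination = NULL) {
  stopifnot(is(truth, "SyntheticTruth"))
  cfg <- truth@config
  if (is.null(read_mode)) read_mode <- cfg$read_mode
  if (is.null(error_rate)) error_rate <- cfg$substitution_error_rate
  if (is.null(contamination)) contamination <- cfg$cross_contamination_fraction
  set.seed(.stageSeed(seed, 3L))
  spike <- truth@pool$spike
  clones <- aggregateTruth(truth)
  samples <- truth@samples$sample
  per_sample <- lapply(samples, function(s) {
    cl <- clones[clones$sample == s, , drop = FALSE]
    spk <- data.frame(sample = s, sgID = spike$sgID,
                      barcode = renderCassette(spike$barcodes),
                      cells = spike$cells_per_line)
    all <- rbind(cl, spk)
    expected <- cfg$read_depth * all$cells / sum(all$cells)
    all$reads <- switch(read_mode,
      expected = expected,
      poisson = rpois(nrow(all), expected),
      multinomial = as.vector(rmultinom(1L, as.integer(round(cfg$read_depth)),
                                        all$cells / sum(all$cells)))
    )
    all$cells <- NULL
    all[all$reads > 0, , drop = FALSE]
  })
  counts <- do.call(rbind, per_sample)
  rownames(counts) <- NULL

  integer_reads <- read_mode != "expected"
  if (error_rate > 0 && integer_reads && nrow(counts)) {
    p_any <- 1 - (1 - error_rate)^30
    nmut <- rbinom(nrow(counts), counts$reads, p_any)
    idx <- which(nmut > 0L)
    if (length(idx)) {
      counts$reads[idx] <- counts$reads[idx] - nmut[idx]
      mut <- data.frame(
        sample = rep(counts$sample[idx], nmut[idx]),
        sgID = rep(counts$sgID[idx], nmut[idx]),
        barcode = .mutateCassettes(rep(counts$barcode[idx], nmut[idx]),
                                   error_rate),
        reads = 1
      )
      counts <- rbind(counts, mut)
    }
  }

  if (contamination > 0 && integer_reads && length(samples) > 1L &&
      nrow(counts)) {
    if (cfg$contamination_mode == "dominant") {
      tumor_rows <- which(counts$sgID != spike$sgID)
      src <- tumor_rows[which.max(counts$reads[tumor_rows])]
      k <- rbinom(1L, counts$reads[src], contamination)
      if (k > 0L) {
        counts$reads[src] <- counts$reads[src] - k
        others <- setdiff(samples, counts$sample[src])
        dest <- as.vector(rmultinom(1L, k, rep(1, length(others))))
        add <- data.frame(sample = others[dest > 0],
                          sgID = counts$sgID[src],
                          barcode = counts$barcode[src],
                          reads = dest[dest > 0])
        counts <- rbind(counts, add)
      }
    } else {
      k <- rbinom(nrow(counts), counts$reads, contamination)
      idx <- which(k > 0L)
      if (length(idx)) {
        counts$reads[idx] <- counts$reads[idx] - k[idx]
        moved <- lapply(idx, function(i) {
          others <- setdiff(samples, counts$sample[i])
          dest <- as.vector(rmultinom(1L, k[i], rep(1, length(others))))
          data.frame(sample = others[dest > 0], sgID = counts$sgID[i],
                     barcode = counts$barcode[i], reads = dest[dest > 0])
        })
        counts <- rbind(counts, do.call(rbind, moved))
      }
    }
  }

  dt <- data.table::as.data.table(counts[counts$reads > 0, , drop = FALSE])
  out <- dt[, list(reads = sum(reads)), by = c("sample", "sgID", "barcode")]
  data.table::setorder(out, sample, sgID, barcode)
  as.data.frame(out)
}

#' Write rendered counts as paired gzipped FASTQ
#'
#' Each read pair carries the 8-nt sgID followed by the 30-nt cassette,
#' embedded at a configurable offset in a constant-context fragment; mate 2
#' is the reverse complement of the fragment, so orientation-aware parsing is
#' exercised.
#'
#' @param counts rendered counts (`sample`, `sgID`, `barcode`, `reads`).
#' @param dir output directory; files are `<sample>_R1.fastq.gz` and
#'   `<sample>_R2.fastq.gz`.
#' @param offset 0-based position of the sgID within the fragment.
#' @param read_length fragment/read length.
#' @return invisible character vector of files written.
#' @export
writeFastqPairs <- function(counts, dir, offset = 10L, read_length = 150L) {
  stopifnot(read_length >= offset + 38L)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  prefix <- paste(rep("T", offset), collapse = "")
  files <- character(0)
  for (s in unique(counts$sample)) {
    cs <- counts[counts$sample == s, , drop = FALSE]
    frag <- paste0(prefix, cs$sgID, cs$barcode)
    frag <- vapply(frag, function(f)
      paste0(f, paste(rep("A", read_length - nchar(f)), collapse = "")),
      character(1), USE.NAMES = FALSE)
    r1 <- rep(frag, cs$reads)
    ids <- sprintf("%s_read%06d", s, seq_along(r1))
    s1 <- Biostrings::DNAStringSet(r1)
    names(s1) <- ids
    s2 <- Biostrings::reverseComplement(s1)
    names(s2) <- ids
    f1 <- file.path(dir, paste0(s, "_R1.fastq.gz"))
    f2 <- file.path(dir, paste0(s, "_R2.fastq.gz"))
    q1 <- Biostrings::QualityScaledDNAStringSet(
      s1, Biostrings::PhredQuality(vapply(nchar(r1), function(n)
        paste(rep("I", n), collapse = ""), character(1))))
    q2 <- Biostrings::QualityScaledDNAStringSet(
      s2, Biostrings::PhredQuality(vapply(nchar(r1), function(n)
        paste(rep("I", n), collapse = ""), character(1))))
    Biostrings::writeQualityScaledXStringSet(q1, f1, compress = TRUE)
    Biostrings::writeQualityScaledXStringSet(q2, f2, compress = TRUE)
    files <- c(files, f1, f2)
  }
  invisible(files)
}
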