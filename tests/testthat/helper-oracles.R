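# Independent oracles and fixture builders shared across tests.

# Brute-force reference for the spurious-barcode collapse: explicit loops,
# greedy in descending read order, merging each small record into its
# largest surviving neighbor within the Hamming radius.
oracleCollapse <- function(barcode, reads, max_distance = 2L,
                          read_fraction = 0.05) {
  hd <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  ord <- order(-reads, barcode)
  bc <- barcode[ord]
  r <- reads[ord]
  alive <- rep(TRUE, length(bc))
  if (length(bc) >= 2) {
    for (i in 2:length(bc)) {
      best <- NA_integer_
      for (j in seq_len(i - 1L)) {
        if (!alive[j]) next
        if (hd(bc[i], bc[j]) > max_distance) next
        if (!(r[i] < read_fraction * r[j])) next
        if (is.na(best) || r[j] > r[best] ||
            (r[j] == r[best] && bc[j] < bc[best])) best <- j
      }
      if (!is.na(best)) {
        r[best] <- r[best] + r[i]
        alive[i] <- FALSE
      }
    }
  }
  out <- data.frame(barcode = bc[alive], reads = r[alive])
  out[order(out$barcode), , drop = FALSE]
}

# Random 20-nt barcodes concentrated on a small alphabet of positions so
# that Hamming-close pairs actually occur.
randomCloseBarcodes <- function(n, n_centers = max(2L, n %/% 10L)) {
  centers <- replicate(n_centers,
    paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = ""))
  vapply(seq_len(n), function(i) {
    b <- strsplit(sample(centers, 1), "")[[1]]
    k <- sample(0:3, 1)
    if (k > 0) {
      pos <- sample(20, k)
      b[pos] <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
    }
    paste(b, collapse = "")
  }, character(1))
}

# A small calibrated TumorSet built directly (no simulation): `sizes` is a
# named list mouse -> list(sgID -> numeric cells).
makeTumorSet <- function(sizes, cohorts = NULL, titer = 1000, cas9 = TRUE) {
  rows <- list()
  for (m in names(sizes)) {
    for (g in names(sizes[[m]])) {
      cells <- sizes[[m]][[g]]
      if (!length(cells)) next
      n <- length(cells)
      bc <- renderCassette(vapply(seq_len(n), function(i)
        paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE),
              collapse = ""), character(1)))
      rows[[length(rows) + 1L]] <- data.frame(
        sample = m, sgID = g, barcode = bc,
        reads = as.numeric(cells), cells = as.numeric(cells))
    }
  }
  tumors <- do.call(rbind, rows)
  mice <- names(sizes)
  if (is.null(cohorts)) cohorts <- setNames(rep("c1", length(mice)), mice)
  samples <- data.frame(sample = mice, cohort = unname(cohorts[mice]),
                        age_group = unname(cohorts[mice]),
                        titer = titer, cas9 = cas9)
  TumorSet(tumors, samples)
}

# Minimal vector table used by stats tests: three inerts + targeted genes.
statsVectors <- function(genes = c("GeneA", "GeneB")) {
  base <- data.frame(
    sgID = c("AAAACCCC", "CCCCAAAA", "GGGGTTTT"),
    sgRNA = c("sgNT1", "sgNT2", "sgNT3"),
    gene = c("NT1", "NT2", "NT3"),
    class = "inert")
  pool <- c("TTTTGGGG", "AAAAGGGG", "GGGGAAAA", "CCCCTTTT", "TTTTCCCC")
  if (!length(genes)) return(VectorSet(base))
  tg <- data.frame(sgID = pool[seq_along(genes)],
                   sgRNA = paste0("sg", genes, "1"),
                   gene = genes, class = "targeting")
  VectorSet(rbind(base, tg))
}

# Equal-proportion sampling plan over the sgIDs present in a TumorSet.
flatPlan <- function(ts, n_per_sg, bench_cohort = NULL) {
  sa <- sampleInfo(ts)
  cohorts <- unique(sa$cohort)
  if (is.null(bench_cohort)) bench_cohort <- cohorts[1]
  sgs <- sort(unique(tumors(ts)$sgID))
  props <- data.frame(sgID = sgs, p = 1 / length(sgs))
  cohort_tab <- do.call(rbind, lapply(cohorts, function(co)
    data.frame(cohort = co, titer_total = sum(sa$titer[sa$cohort == co]))))
  # equal titers in the helper: quotas equal n_per_sg everywhere
  cohort_tab$titer_total <- cohort_tab$titer_total[1]
  computeSamplingPlan(sgs[1], bench_cohort, n_per_sg, cohort_tab, props)
}
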