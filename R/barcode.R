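#' Parse paired reads into an sgID-barcode tally
#'
#' Locates the 30-nt GC/TA-spacer cassette (and the 8-nt sgID immediately
#' upstream) in each mate with a regular expression; mate 2 is
#' reverse-complemented before scanning. A pair contributes one count only
#' when both mates yield an identical sgID-barcode string; all other pairs
#' are dropped and counted by reason.
#'
#' @param r1,r2 character vectors of mate sequences, or paths to (optionally
#'   gzipped) FASTQ files.
#' @return list with `counts` (data.frame `sgID_seq`, `barcode`, `reads`)
#'   and `dropped` (named integer: `no_match`, `mate_mismatch`).
#' @export
parseReadPairs <- function(r1, r2) {
  r1 <- .readSeqs(r1)
  r2 <- .readSeqs(r2)
  if (length(r1) != length(r2))
    .stopData("mate files differ in read count (", length(r1), " vs ",
              length(r2), ")")
  r2 <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(r2)))
  hit1 <- .extractCassette(r1)
  hit2 <- .extractCassette(r2)
  no_match <- is.na(hit1) | is.na(hit2)
  concordant <- !no_match & hit1 == hit2
  mate_mismatch <- !no_match & !concordant
  tal <- table(hit1[concordant])
  counts <- data.frame(
    sgID_seq = substr(names(tal), 1, 8),
    barcode = substr(names(tal), 9, 38),
    reads = as.integer(tal)
  )
  rownames(counts) <- NULL
  list(counts = counts,
       dropped = c(no_match = sum(no_match),
                   mate_mismatch = sum(mate_mismatch)))
}

.readSeqs <- function(x) {
  if (length(x) == 1L && file.exists(x) &&
      grepl("\\.(fastq|fq)(\\.gz)?$", x)) {
    ss <- Biostrings::readDNAStringSet(x, format = "fastq")
    return(as.character(ss, use.names = FALSE))
  }
  as.character(x)
}

# 38-nt sgID+cassette string per read, NA where the frame is absent. The
# match must start at least 8 nt in so the sgID is fully present.
.extractCassette <- function(reads) {
  m <- regexpr(.BC_TEMPLATE_REGEX, reads)
  start <- as.integer(m)
  ok <- start >= 9L
  out <- rep(NA_character_, length(reads))
  out[ok] <- paste0(substr(reads[ok], start[ok] - 8L, start[ok] - 1L),
                    substr(reads[ok], start[ok], start[ok] + 29L))
  out[ok & !grepl("^[ACGT]{8}$", substr(out, 1, 8))] <- NA_character_
  out
}

#' Assign parsed sgID sequences to vectors
#'
#' Exact-match assignment by default: because sgIDs in a pool differ by at
#' least three nucleotides and mates must already agree, single-error
#' correction adds nothing. A mismatch-tolerant mode (distance <= 1 to a
#' unique table entry) is available behind `max_mismatch`.
#'
#' @param sgid_seq character vector of observed 8-nt sgID sequences.
#' @param vectors a [VectorSet-class] or its info data.frame.
#' @param max_mismatch 0 (default, exact) or 1.
#' @return character vector of assigned sgIDs, NA where rejected.
#' @export
assignSgids <- function(sgid_seq, vectors, max_mismatch = 0L) {
  info <- if (is(vectors, "VectorSet")) vectorInfo(vectors) else vectors
  out <- info$sgID[match(sgid_seq, info$sgID)]
  if (max_mismatch >= 1L && any(is.na(out)) && nrow(info)) {
    miss <- which(is.na(out) & nchar(sgid_seq) == 8L &
                    grepl("^[ACGT]{8}$", sgid_seq))
    if (length(miss)) {
      tab <- .charMatrix(info$sgID)
      for (i in miss) {
        d <- colSums(tab != matrix(charToRaw(sgid_seq[i]), nrow = 8L,
                                   ncol = ncol(tab)))
        hit <- which(d <= max_mismatch)
        if (length(hit) == 1L) out[i] <- info$sgID[hit]
      }
    }
  }
  out
}

#' Collapse spurious neighbor barcodes within a sample
#'
#' Sequencing/PCR errors spawn small satellite "tumors" whose barcodes sit
#' within Hamming distance two of a genuine large tumor. Within each
#' (sample, sgID) group, records are processed in descending read order;
#' a record whose reads are fewer than 5% of a surviving record at Hamming
#' distance <= 2 is merged into the largest such neighbor (ties broken by
#' lexicographically smaller barcode). Merged records cannot re-merge, and
#' total reads are conserved.
#'
#' @param counts data.frame with columns `sample`, `sgID`, `barcode`,
#'   `reads` (plus any extra columns, which are retained for survivors).
#' @param max_distance Hamming radius (default 2).
#' @param read_fraction relative-size threshold (default 0.05; strict `<`).
#' @param informative_only compare only the 20 degenerate positions
#'   (default) rather than the full 30-nt cassette.
#' @return list with `counts` (collapsed records) and `n_collapsed`
#'   (number of merged records).
#' @export
collapseSpurious <- function(counts, max_distance = 2L, read_fraction = 0.05,
                             informative_only = TRUE) {
  if (!nrow(counts))
    return(list(counts = counts, n_collapsed = 0L))
  dt <- data.table::as.data.table(counts)
  grp <- dt[, .GRP, by = c("sample", "sgID")]$GRP
  key <- paste(dt$sample, dt$sgID)
  pieces <- split(seq_len(nrow(dt)), key)
  keep_rows <- vector("list", length(pieces))
  new_reads <- dt$reads
  merged_total <- 0L
  for (g in seq_along(pieces)) {
    ix <- pieces[[g]]
    res <- .collapseGroup(dt$barcode[ix], dt$reads[ix], max_distance,
                          read_fraction, informative_only)
    keep_rows[[g]] <- ix[res$keep]
    new_reads[ix] <- res$reads
    merged_total <- merged_total + sum(!res$keep)
  }
  keep <- sort(unlist(keep_rows, use.names = FALSE))
  out <- as.data.frame(dt[keep])
  out$reads <- new_reads[keep]
  rownames(out) <- NULL
  list(counts = out, n_collapsed = merged_total)
}

# Greedy collapse of one (sample, sgID) group. Returns keep flags and
# updated reads aligned to the input order.
.collapseGroup <- function(barcode, reads, max_distance, read_fraction,
                           informative_only) {
  n <- length(barcode)
  if (n < 2L) return(list(keep = rep(TRUE, n), reads = reads))
  cmp <- if (informative_only && all(nchar(barcode) == 30L))
    informativeBarcode(barcode) else barcode
  ord <- order(-reads, barcode)
  m <- .charMatrix(cmp[ord])
  r <- reads[ord]
  bc <- barcode[ord]
  alive <- rep(TRUE, n)
  for (i in 2:n) {
    prev <- which(alive[seq_len(i - 1L)])
    if (!length(prev)) next
    d <- colSums(m[, prev, drop = FALSE] != m[, i])
    cand <- prev[d <= max_distance & r[i] < read_fraction * r[prev]]
    if (!length(cand)) next
    # largest surviving neighbor; ties -> lexicographically smaller barcode
    best <- cand[order(-r[cand], bc[cand])][1L]
    r[best] <- r[best] + r[i]
    r[i] <- 0
    alive[i] <- FALSE
  }
  keep <- logical(n)
  keep[ord] <- alive
  out_reads <- numeric(n)
  out_reads[ord] <- r
  list(keep = keep, reads = out_reads)
}

#' Calibrate read counts to absolute cell numbers via spike-ins
#'
#' Three benchmark spike-in cell lines of known cell number are added to
#' each sample before DNA extraction; the pooled ratio of spike-in cells to
#' spike-in reads converts every tumor's reads to absolute neoplastic cell
#' number. Spike-in records are removed from the tumor table. Per-line
#' factors are retained for QC.
#'
#' @param counts data.frame (`sample`, `sgID`, `barcode`, `reads`).
#' @param spike list with `sgID`, `barcodes` (20-nt), `cells_per_line`.
#' @return list with `counts` (tumor records with `cells`), and `qc`
#'   (per-sample data.frame of calibration factors and per-line reads).
#' @export
normalizeToCells <- function(counts, spike) {
  spike_bc30 <- renderCassette(spike$barcodes)
  out <- vector("list", 0L)
  qc <- vector("list", 0L)
  for (s in unique(counts$sample)) {
    cs <- counts[counts$sample == s, , drop = FALSE]
    spike_sgid <- cs$sgID == spike$sgID
    is_spike <- spike_sgid & cs$barcode %in% spike_bc30
    spk <- cs[is_spike, , drop = FALSE]
    line_reads <- spk$reads[match(spike_bc30, spk$barcode)]
    if (any(is.na(line_reads) | line_reads <= 0)) {
      missing <- which(is.na(line_reads) | line_reads <= 0)[1L]
      .stopData(sprintf(
        "spike-in line %d (%s) absent or zero reads in sample %s: cannot calibrate",
        missing, spike$barcodes[missing], s))
    }
    total_cells <- spike$cells_per_line * length(spike$barcodes)
    factor <- total_cells / sum(line_reads)
    # rows under the spike sgID that are not a known line (error residue)
    # carry no tumor identity and are dropped
    tum <- cs[!spike_sgid, , drop = FALSE]
    tum$cells <- tum$reads * factor
    out[[length(out) + 1L]] <- tum
    qc[[length(qc) + 1L]] <- data.frame(
      sample = s, factor = factor,
      t(setNames(spike$cells_per_line / line_reads,
                 paste0("line_factor_", seq_along(line_reads)))))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  list(counts = res, qc = do.call(rbind, qc))
}

#' Process a rendered count table into a calibrated TumorSet
#'
#' Validates barcode templates, assigns sgIDs (exact match), collapses
#' spurious neighbor barcodes within samples, and calibrates to absolute
#' cell numbers with the spike-ins.
#'
#' @param counts data.frame (`sample`, `sgID`, `barcode`, `reads`) as
#'   produced by [renderReads()] or [parseReadPairs()] tallies combined
#'   across samples.
#' @param vectors a [VectorSet-class] or vector info data.frame.
#' @param spike spike-in spec (list with `sgID`, `barcodes`,
#'   `cells_per_line`).
#' @param samples sample metadata data.frame (see [TumorSet()]).
#' @param max_mismatch sgID mismatch tolerance (default 0 = exact).
#' @param informative_only Hamming comparisons on the 20 informative nt.
#' @return list with `tumors` (a calibrated [TumorSet-class]) and `qc`
#'   (drop counts, collapse count, calibration factors).
#' @export
processCounts <- function(counts, vectors, spike, samples,
                          max_mismatch = 0L, informative_only = TRUE) {
  info <- if (is(vectors, "VectorSet")) vectorInfo(vectors) else vectors
  n0 <- nrow(counts)
  ok_template <- .isValidCassette(counts$barcode)
  counts <- counts[ok_template, , drop = FALSE]
  assigned <- assignSgids(counts$sgID, info, max_mismatch = max_mismatch)
  is_spike <- counts$sgID == spike$sgID
  keep <- !is.na(assigned) | is_spike
  dropped_sgid <- sum(!keep)
  counts <- counts[keep, , drop = FALSE]
  counts$sgID[!is_spike[keep]] <- assigned[keep][!is_spike[keep]]
  # collapse within sgID covers spike-in lines too (their error satellites
  # merge back into the line record)
  cl <- collapseSpurious(counts, informative_only = informative_only)
  norm <- normalizeToCells(cl$counts, spike)
  ts <- TumorSet(norm$counts[, c("sample", "sgID", "barcode", "reads",
                                 "cells")], samples)
  list(tumors = ts,
       qc = list(n_input = n0,
                 dropped_template = sum(!ok_template),
                 dropped_sgid = dropped_sgid,
                 n_collapsed = cl$n_collapsed,
                 calibration = norm$qc))
}
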