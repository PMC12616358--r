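test_that("concordant mate pairs are tallied; discordant and frameless dropped", {
  cassette <- "GCAAAAATACCCCCGCGGGGGTATTTTTGC"
  good <- paste0("TTTTTTTTTT", "AAGGTTCC", cassette, "AAAAAA")
  rc <- function(x)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  # pair 1: both mates agree; pair 2: mate 2 differs at one barcode base;
  # pair 3: no GC/TA frame at all
  bad_mate <- sub("GCAAAAATA", "GCAAAAGTA", good)
  no_frame <- paste0(strrep("T", 10), "AAGGTTCC", strrep("AC", 20))
  res <- parseReadPairs(c(good, good, no_frame),
                        c(rc(good), rc(bad_mate), rc(no_frame)))
  expect_identical(res$counts$sgID_seq, "AAGGTTCC")
  expect_identical(res$counts$barcode, cassette)
  expect_identical(res$counts$reads, 1L)
  expect_identical(res$dropped, c(no_match = 1L, mate_mismatch = 1L))
})

test_that("FASTQ pairs written by the renderer parse back to the same tally", {
  cfg <- demoConfig(n_mice = 2L, read_depth = 400)
  truth <- simulateTruth(cfg, seed = 31)
  counts <- renderReads(truth, seed = 31, error_rate = 0, contamination = 0)
  dir <- tempfile("fq")
  writeFastqPairs(counts, dir)
  s <- counts$sample[1]
  res <- parseReadPairs(file.path(dir, paste0(s, "_R1.fastq.gz")),
                        file.path(dir, paste0(s, "_R2.fastq.gz")))
  got <- res$counts[order(res$counts$sgID_seq, res$counts$barcode), ]
  want <- counts[counts$sample == s, ]
  want <- want[order(want$sgID, want$barcode), ]
  expect_identical(got$sgID_seq, want$sgID)
  expect_identical(got$barcode, want$barcode)
  expect_identical(got$reads, as.integer(want$reads))
  expect_identical(unname(res$dropped), c(0L, 0L))
  unlink(dir, recursive = TRUE)
})

test_that("sgID assignment is exact-match with optional 1-mismatch mode", {
  info <- data.frame(sgID = c("AAGGTTCC", "GGCCAATT"),
                     sgRNA = c("sg1", "sg2"), gene = c("A", "B"),
                     class = "targeting")
  expect_identical(assignSgids(c("AAGGTTCC", "AAGGTTCA", "TTTTTTTT"), info),
                   c("AAGGTTCC", NA, NA))
  expect_identical(assignSgids("AAGGTTCA", info, max_mismatch = 1L),
                   "AAGGTTCC")
  empty <- info[0, ]
  expect_identical(assignSgids("AAGGTTCC", empty), NA_character_)
})

test_that("collapse merges small Hamming-neighbors per the 5% rule", {
  b1 <- renderCassette(strrep("A", 20))
  b2 <- renderCassette(paste0("T", strrep("A", 19)))       # distance 1
  df <- data.frame(sample = "m1", sgID = "AAGGTTCC",
                   barcode = c(b1, b2), reads = c(10000, 400))
  out <- collapseSpurious(df)
  expect_identical(nrow(out$counts), 1L)
  expect_identical(out$counts$reads, 10400)
  expect_identical(out$counts$barcode, b1)
  expect_identical(out$n_collapsed, 1L)
  # 600 >= 5% of 10000: both retained
  df2 <- df; df2$reads <- c(10000, 600)
  out2 <- collapseSpurious(df2)
  expect_identical(nrow(out2$counts), 2L)
})

test_that("collapse chains follow greedy descending order without re-merging", {
  bA <- renderCassette(strrep("A", 20))
  bB <- renderCassette(paste0("T", strrep("A", 19)))       # 1 from A
  bC <- renderCassette(paste0("TC", strrep("A", 18)))      # 1 from B, 2 from A
  df <- data.frame(sample = "m1", sgID = "AAGGTTCC",
                   barcode = c(bA, bB, bC), reads = c(10000, 300, 10))
  out <- collapseSpurious(df)
  oracle <- oracleCollapse(informativeBarcode(df$barcode), df$reads)
  expect_identical(nrow(out$counts), nrow(oracle))
  expect_identical(sum(out$counts$reads), 10310)
  # C at distance 3 from A, only neighbor B already merged: C survives
  bC2 <- renderCassette(paste0("TCG", strrep("A", 17)))
  df2 <- data.frame(sample = "m1", sgID = "AAGGTTCC",
                    barcode = c(bA, bB, bC2), reads = c(10000, 300, 10))
  out2 <- collapseSpurious(df2)
  expect_setequal(out2$counts$barcode, c(bA, bC2))
})

test_that("collapse equals the brute-force oracle on random instances", {
  set.seed(55)
  for (rep in 1:60) {
    n <- sample(2:120, 1)
    bc20 <- randomCloseBarcodes(n)
    reads <- pmax(1, round(rlnorm(n, 5, 2.5)))
    df <- data.frame(sample = "m1", sgID = "AAGGTTCC",
                     barcode = renderCassette(bc20), reads = reads)
    out <- collapseSpurious(df)
    oracle <- oracleCollapse(bc20, reads)
    oracle <- oracle[order(oracle$barcode, oracle$reads), ]
    got <- out$counts[order(informativeBarcode(out$counts$barcode),
                            out$counts$reads), ]
    expect_identical(informativeBarcode(got$barcode), oracle$barcode)
    expect_identical(as.numeric(got$reads), as.numeric(oracle$reads))
    expect_identical(sum(out$counts$reads), sum(df$reads))  # conservation
  }
})

test_that("collapse conserves reads per sample and sgID", {
  set.seed(56)
  df <- do.call(rbind, lapply(c("m1", "m2"), function(m)
    do.call(rbind, lapply(c("AAGGTTCC", "GGCCAATT"), function(g)
      data.frame(sample = m, sgID = g,
                 barcode = renderCassette(randomCloseBarcodes(50)),
                 reads = pmax(1, round(rlnorm(50, 5, 2))))))))
  out <- collapseSpurious(df)
  before <- tapply(df$reads, paste(df$sample, df$sgID), sum)
  after <- tapply(out$counts$reads, paste(out$counts$sample,
                                          out$counts$sgID), sum)
  expect_equal(as.vector(after[names(before)]), as.vector(before))
})

test_that("spike-in calibration converts reads to absolute cells", {
  spike <- list(sgID = "AAAATTTT",
                barcodes = c(strrep("A", 20), strrep("C", 20),
                             strrep("G", 20)),
                cells_per_line = 1e5)
  mk <- function(spike_reads, tumor_reads = 5000) {
    rbind(
      data.frame(sample = "m1", sgID = "AAGGTTCC",
                 barcode = renderCassette(strrep("T", 20)),
                 reads = tumor_reads),
      data.frame(sample = "m1", sgID = spike$sgID,
                 barcode = renderCassette(spike$barcodes),
                 reads = spike_reads))
  }
  # 300,000 spike reads against 300,000 cells: factor 1
  r1 <- normalizeToCells(mk(rep(1e5, 3)), spike)
  expect_equal(r1$counts$cells, 5000)
  # 600,000 spike reads: factor 0.5
  r2 <- normalizeToCells(mk(rep(2e5, 3)), spike)
  expect_equal(r2$counts$cells, 2500)
  expect_equal(r2$qc$factor, 0.5)
  # scaling all reads by a constant leaves cells unchanged
  r3 <- normalizeToCells(mk(rep(3e5, 3), tumor_reads = 7500), spike)
  r4 <- normalizeToCells(mk(rep(6e5, 3), tumor_reads = 15000), spike)
  expect_equal(r3$counts$cells, r4$counts$cells)
  # a missing line is a calibration error naming line and sample
  bad <- mk(c(1e5, 0, 1e5))
  expect_error(normalizeToCells(bad, spike), "line 2",
               class = "clonequant_data_error")
  expect_error(normalizeToCells(bad, spike), "m1",
               class = "clonequant_data_error")
})

test_that("noiseless synthetic data round-trips through processing exactly", {
  cfg <- demoConfig(n_mice = 2L, read_depth = 4e4)
  truth <- simulateTruth(cfg, seed = 41)
  counts <- renderReads(truth, seed = 41, read_mode = "expected",
                        error_rate = 0, contamination = 0)
  vec <- VectorSet(cfg$vectors[c("sgID", "sgRNA", "gene", "class")])
  proc <- processCounts(counts, vec, truth@pool$spike, sampleInfo(truth))
  tru <- aggregateTruth(truth)
  got <- tumors(proc$tumors)
  got <- got[order(got$sample, got$sgID, got$barcode), ]
  expect_identical(paste(got$sample, got$sgID, got$barcode),
                   paste(tru$sample, tru$sgID, tru$barcode))
  expect_equal(got$cells, tru$cells, tolerance = 1e-9)
  expect_identical(proc$qc$n_collapsed, 0L)
})

test_that("template-violating barcodes are dropped and counted", {
  spike <- list(sgID = "AAAATTTT",
                barcodes = c(strrep("A", 20), strrep("C", 20),
                             strrep("G", 20)),
                cells_per_line = 1e5)
  vec <- data.frame(sgID = "AAGGTTCC", sgRNA = "sg1", gene = "A",
                    class = "targeting")
  counts <- rbind(
    data.frame(sample = "m1", sgID = "AAGGTTCC",
               barcode = renderCassette(strrep("T", 20)), reads = 100),
    data.frame(sample = "m1", sgID = "AAGGTTCC",
               barcode = paste0("TT", substr(renderCassette(strrep("T", 20)),
                                             3, 30)),  # broken GC spacer
               reads = 50),
    data.frame(sample = "m1", sgID = spike$sgID,
               barcode = renderCassette(spike$barcodes), reads = 1000))
  samples <- data.frame(sample = "m1", cohort = "c", age_group = "young",
                        titer = 100, cas9 = TRUE)
  proc <- processCounts(counts, vec, spike, samples)
  expect_identical(proc$qc$dropped_template, 1L)
  expect_identical(nrow(tumors(proc$tumors)), 1L)
})
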