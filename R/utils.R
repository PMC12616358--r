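#' @importFrom stats median ppois dpois quantile rlnorm rpois rbinom rmultinom
#'   runif uniroot var setNames p.adjust ks.test
#' @importFrom utils head read.delim write.table
#' @importFrom methods new validObject is slot
#' @import data.table
#' @useDynLib clonequant, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Cassette geometry: 30-nt barcode region GCNNNNNTANNNNNGCNNNNNTANNNNNGC.
# The 20 Ns sit at these 1-based positions within the 30-mer.
.BC_TEMPLATE_REGEX <- "GC[ACGT]{5}TA[ACGT]{5}GC[ACGT]{5}TA[ACGT]{5}GC"
.BC_N_POSITIONS <- c(3:7, 10:14, 17:21, 24:28)
.CASSETTE_REGEX <- paste0("([ACGT]{8})(", .BC_TEMPLATE_REGEX, ")")

.DNA <- c("A", "C", "G", "T")

#' Render a 20-nt informative barcode into the 30-nt cassette form
#'
#' The sequenced barcode region is a 30-nt string in which fixed GC/TA
#' spacers frame four blocks of five degenerate nucleotides. This helper
#' interleaves a 20-nt informative barcode with those spacers.
#'
#' @param bc20 character vector of 20-nt barcodes (A/C/G/T).
#' @return character vector of 30-nt cassette barcodes.
#' @export
renderCassette <- function(bc20) {
  stopifnot(all(nchar(bc20) == 20L))
  paste0(
    "GC", substr(bc20, 1, 5),
    "TA", substr(bc20, 6, 10),
    "GC", substr(bc20, 11, 15),
    "TA", substr(bc20, 16, 20),
    "GC"
  )
}

#' Extract the 20 informative nucleotides from a 30-nt cassette barcode
#'
#' @param bc30 character vector of 30-nt cassette barcodes.
#' @return character vector of 20-nt informative barcodes.
#' @export
informativeBarcode <- function(bc30) {
  stopifnot(all(nchar(bc30) == 30L))
  paste0(
    substr(bc30, 3, 7), substr(bc30, 10, 14),
    substr(bc30, 17, 21), substr(bc30, 24, 28)
  )
}

# TRUE where the 30-mer conforms to the fixed-spacer template.
.isValidCassette <- function(bc30) {
  nchar(bc30) == 30L & grepl(paste0("^", .BC_TEMPLATE_REGEX, "$"), bc30)
}

#' Hamming distance between equal-length DNA strings
#'
#' @param a,b character vectors of equal-length strings; `b` is recycled
#'   against `a`.
#' @return integer vector of pairwise distances.
#' @export
hammingDistance <- function(a, b) {
  if (length(b) == 1L) b <- rep(b, length(a))
  stopifnot(length(a) == length(b), all(nchar(a) == nchar(b)))
  ra <- lapply(a, charToRaw)
  rb <- lapply(b, charToRaw)
  mapply(function(x, y) sum(x != y), ra, rb, USE.NAMES = FALSE)
}

# Character matrix (positions x n) for fast columnwise Hamming comparisons.
.charMatrix <- function(x) {
  n <- length(x)
  if (n == 0L) return(matrix(raw(0), nrow = 0, ncol = 0))
  matrix(unlist(lapply(x, charToRaw), use.names = FALSE),
         nrow = nchar(x[1L]), ncol = n)
}

# All pairwise sgIDs must differ by >= 3 nt; returns NULL or the offending
# pair as a character vector of length 2.
.sgidCollision <- function(sgids) {
  n <- length(sgids)
  if (n < 2L) return(NULL)
  m <- .charMatrix(sgids)
  for (i in seq_len(n - 1L)) {
    d <- colSums(m[, (i + 1L):n, drop = FALSE] != m[, i])
    bad <- which(d < 3L)
    if (length(bad)) return(c(sgids[i], sgids[i + bad[1L]]))
  }
  NULL
}

# Random DNA strings of length `len` (distinct within the returned set).
.randomBarcodes <- function(n, len) {
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    m <- matrix(sample(.DNA, need * len, replace = TRUE), ncol = len)
    fresh <- do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
    out <- unique(c(out, fresh))
  }
  out[seq_len(n)]
}

# Per-stage seed derivation from a root seed. Stage indices are small
# integers; results stay within 32-bit range.
.stageSeed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 97 + stage * 1009) %% 2147483647)
}

.stopData <- function(...) {
  stop(errorCondition(paste0(...), class = c("clonequant_data_error", "error")))
}

.stopConfig <- function(...) {
  stop(errorCondition(paste0(...), class = c("clonequant_config_error", "error")))
}
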