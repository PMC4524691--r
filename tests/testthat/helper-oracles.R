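# Independent oracles used across the suite.  Each one recomputes a
# quantity by brute force (per-base boolean arrays, exhaustive DP,
# sliding windows) without touching the package's own code paths.

# per-base coverage oracle: mark every covered base in a logical vector
oracle_covered_bases <- function(starts, ends, region_start, region_end) {
  len <- region_end - region_start + 1L
  hit <- logical(len)
  for (i in seq_along(starts)) {
    lo <- max(starts[i], region_start)
    hi <- min(ends[i], region_end)
    if (lo <= hi) hit[(lo - region_start + 1L):(hi - region_start + 1L)] <- TRUE
  }
  sum(hit)
}

# per-base merged intervals oracle on [1, len]
oracle_merge <- function(starts, ends, len) {
  hit <- logical(len)
  for (i in seq_along(starts)) hit[starts[i]:ends[i]] <- TRUE
  r <- rle(hit)
  stops <- cumsum(r$lengths)
  begins <- stops - r$lengths + 1L
  data.frame(start = begins[r$values], end = stops[r$values])
}

# Gotoh affine-gap DP, global, score only; a gap of length L costs
# open + L * ext (the package's scoring convention)
oracle_global_score <- function(a, b, match = 5, mismatch = -4,
                                open = 16, ext = 4) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in b (consume a)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a (consume b)
  M[1, 1] <- 0
  for (i in seq_len(n) + 1)
    X[i, 1] <- -open - (i - 1) * ext
  for (j in seq_len(m) + 1)
    Y[1, j] <- -open - (j - 1) * ext
  for (i in seq_len(n) + 1) {
    for (j in seq_len(m) + 1) {
      s <- if (a[i - 1] == b[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1],
                     Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# sliding-window Hamming scan: all start positions where pattern
# matches subject with <= maxmm substitutions
oracle_hamming_scan <- function(pattern, subject, maxmm = 0) {
  p <- strsplit(pattern, "")[[1]]
  s <- strsplit(subject, "")[[1]]
  if (length(s) < length(p)) return(integer(0))
  hits <- integer(0)
  for (i in 1:(length(s) - length(p) + 1)) {
    mm <- sum(p != s[i:(i + length(p) - 1)])
    if (mm <= maxmm) hits <- c(hits, i)
  }
  hits
}

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

# sliding-window IUPAC scan; subject N never matches (counts mismatch)
oracle_iupac_scan <- function(pattern, subject, maxmm) {
  p <- strsplit(pattern, "")[[1]]
  s <- strsplit(subject, "")[[1]]
  if (length(s) < length(p)) return(data.frame(start = integer(),
                                               mismatches = integer()))
  out <- list()
  for (i in 1:(length(s) - length(p) + 1)) {
    win <- s[i:(i + length(p) - 1)]
    mm <- sum(vapply(seq_along(p), function(k)
      !(win[k] %in% IUPAC_SETS[[p[k]]]) || win[k] == "N", logical(1)))
    if (mm <= maxmm)
      out[[length(out) + 1L]] <- data.frame(start = i, mismatches = mm)
  }
  if (length(out) == 0) return(data.frame(start = integer(),
                                          mismatches = integer()))
  do.call(rbind, out)
}

revcomp_str <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

rand_dna_str <- function(n)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

# quick GRanges builder on a single test chromosome
gr1 <- function(starts, ends, chrom = "chr1", strand = "*", ...) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, ends),
                         strand = strand, ...)
}
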