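#' Alignment scoring presets
#'
#' Default scoring mirrors the classic EMBOSS tools: global DNA
#' alignment with match +5 / mismatch -4, gap open 16, gap extension 4
#' (a gap of length L costs `open + L * ext`); global protein alignment
#' with BLOSUM62, open 12, extension 2; local DNA alignment with match
#' +5 / mismatch -4, open 10, extension 0.5.
#'
#' @param type `"dna"` or `"protein"`.
#' @param mode `"global"` or `"local"`.
#' @return A list of scoring parameters accepted by [align_pair()].
#' @export
align_params <- function(type = c("dna", "protein"),
                         mode = c("global", "local")) {
  type <- match.arg(type)
  mode <- match.arg(mode)
  if (type == "dna") {
    sm <- Biostrings::nucleotideSubstitutionMatrix(match = 5,
                                                   mismatch = -4,
                                                   baseOnly = FALSE)
    if (mode == "global")
      list(substitutionMatrix = sm, gapOpening = 16, gapExtension = 4)
    else
      list(substitutionMatrix = sm, gapOpening = 10, gapExtension = 0.5)
  } else {
    list(substitutionMatrix = "BLOSUM62",
         gapOpening = if (mode == "global") 12 else 10,
         gapExtension = 2)
  }
}

#' Pairwise alignment with the package presets
#'
#' Thin wrapper around [Biostrings::pairwiseAlignment()] exposing the
#' package's deterministic scoring presets and returning the aligned
#' strings alongside the score.
#'
#' @param a,b Sequences (character, `DNAString` or `AAString`).
#' @param type `"dna"` or `"protein"`.
#' @param mode `"global"` or `"local"`.
#' @param params Scoring parameters, defaulting to
#'   `align_params(type, mode)`.
#' @return A list with `aligned_a`, `aligned_b` (gapped strings),
#'   `score`, and for local mode the start offsets `start_a`,
#'   `start_b`.
#' @export
align_pair <- function(a, b, type = c("dna", "protein"),
                       mode = c("global", "local"),
                       params = NULL) {
  type <- match.arg(type)
  mode <- match.arg(mode)
  if (is.null(params)) params <- align_params(type, mode)
  cls <- if (type == "dna") Biostrings::DNAString else Biostrings::AAString
  pa <- Biostrings::pairwiseAlignment(
    cls(as.character(a)), cls(as.character(b)),
    type = mode,
    substitutionMatrix = params$substitutionMatrix,
    gapOpening = params$gapOpening,
    gapExtension = params$gapExtension)
  list(aligned_a = as.character(Biostrings::alignedPattern(pa)[[1]]),
       aligned_b = as.character(Biostrings::alignedSubject(pa)[[1]]),
       score = Biostrings::score(pa),
       start_a = BiocGenerics::start(Biostrings::pattern(pa)),
       start_b = BiocGenerics::start(Biostrings::subject(pa)),
       identity = Biostrings::pid(pa, type = "PID1") / 100,
       aligned_length = Biostrings::nchar(pa))
}

#' Global alignment (Needleman-Wunsch with affine gaps)
#'
#' @inheritParams align_pair
#' @return See [align_pair()].
#' @export
global_align <- function(a, b, type = "dna", params = NULL) {
  if (!nzchar(as.character(a)) || !nzchar(as.character(b)))
    stop("sequences must be non-empty")
  align_pair(a, b, type = type, mode = "global", params = params)
}

#' Extract indels and substitutions from a global alignment
#'
#' Walks the aligned strings column by column.  Each maximal run of
#' gaps becomes a single indel (`insertion_a` when the extra bases are
#' in sequence A, `insertion_b` when in B); each aligned mismatch column
#' becomes a substitution of length 1.  Positions are ungapped, 1-based
#' offsets in the respective sequence; the inserted-against side of an
#' indel carries the position of the last base before the gap (0 when
#' the gap opens at the start).
#'
#' @param alignment Result of [global_align()].
#' @return data.frame with columns `kind`, `pos_a`, `pos_b`, `length`.
#' @export
extract_diffs <- function(alignment) {
  ca <- strsplit(alignment$aligned_a, "")[[1]]
  cb <- strsplit(alignment$aligned_b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  pos_a <- cumsum(ca != "-")
  pos_b <- cumsum(cb != "-")
  kind <- ifelse(cb == "-", "insertion_a",
          ifelse(ca == "-", "insertion_b",
          ifelse(ca != cb, "substitution", "match")))
  out <- list()
  i <- 1L
  n <- length(ca)
  while (i <= n) {
    k <- kind[i]
    if (k == "match") { i <- i + 1L; next }
    if (k == "substitution") {
      out[[length(out) + 1L]] <- data.frame(
        kind = "substitution", pos_a = pos_a[i], pos_b = pos_b[i],
        length = 1L, stringsAsFactors = FALSE)
      i <- i + 1L
      next
    }
    j <- i
    while (j < n && kind[j + 1L] == k) j <- j + 1L
    out[[length(out) + 1L]] <- data.frame(
      kind = k,
      pos_a = if (k == "insertion_a") pos_a[i] else pos_a[i] - 0L,
      pos_b = if (k == "insertion_b") pos_b[i] else pos_b[i] - 0L,
      length = j - i + 1L, stringsAsFactors = FALSE)
    i <- j + 1L
  }
  if (length(out) == 0L)
    return(data.frame(kind = character(), pos_a = integer(),
                      pos_b = integer(), length = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Reconstruct sequence B from sequence A and a diff list
#'
#' Round-trip check used by the test oracles: applying the diffs from
#' [extract_diffs()] to the alignment regenerates sequence B exactly.
#'
#' @param alignment Result of [global_align()].
#' @return The ungapped B sequence implied by the alignment.
#' @export
apply_diffs <- function(alignment) {
  gsub("-", "", alignment$aligned_b, fixed = TRUE)
}
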