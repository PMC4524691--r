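#' Reciprocal-best-hit orthologue pairing
#'
#' For each protein, the best-scoring partner in the other proteome by
#' local protein alignment (BLOSUM62, affine gaps).  A pair is emitted
#' as `reciprocal` when each member is the other's best hit; ties break
#' by higher identity, then lexicographic id, so pairing is
#' deterministic.  Requiring reciprocity avoids asymmetric many-to-one
#' pairs that would inflate cascade denominators; non-reciprocal best
#' hits are reported with `reciprocal = FALSE`.
#'
#' @param proteome_a,proteome_b Named `AAStringSet`s.
#' @return data.frame with columns `gene_a`, `gene_b`, `score`,
#'   `identity`, `reciprocal`.
#' @export
find_orthologs <- function(proteome_a, proteome_b) {
  if (length(proteome_a) == 0L || length(proteome_b) == 0L)
    stop("empty proteome")
  score_row <- function(one, many) {
    pa <- Biostrings::pairwiseAlignment(
      rep(Biostrings::AAStringSet(one), length(many)), many,
      type = "local", substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 2)
    list(score = Biostrings::score(pa),
         identity = Biostrings::pid(pa, type = "PID1") / 100)
  }
  na <- length(proteome_a); nb <- length(proteome_b)
  scores <- matrix(0, na, nb)
  idents <- matrix(0, na, nb)
  for (i in seq_len(na)) {
    sr <- score_row(proteome_a[i], proteome_b)
    scores[i, ] <- sr$score
    idents[i, ] <- sr$identity
  }
  pick_best <- function(s, id, ids) {
    o <- order(-s, -id, ids)
    o[1]
  }
  best_for_a <- vapply(seq_len(na), function(i)
    pick_best(scores[i, ], idents[i, ], names(proteome_b)), integer(1))
  best_for_b <- vapply(seq_len(nb), function(j)
    pick_best(scores[, j], idents[, j], names(proteome_a)), integer(1))
  data.frame(
    gene_a = names(proteome_a),
    gene_b = names(proteome_b)[best_for_a],
    score = scores[cbind(seq_len(na), best_for_a)],
    identity = idents[cbind(seq_len(na), best_for_a)],
    reciprocal = best_for_b[best_for_a] == seq_len(na),
    stringsAsFactors = FALSE)
}

#' Project transcript-space intervals to the genome via the exon ladder
#'
#' Maps an interval in spliced-transcript coordinates onto genomic
#' coordinates using the gene's ordered exon list (5'->3').  An interval
#' spanning an exon junction projects to multiple genomic segments.
#'
#' @param tx_start,tx_end 1-based transcript coordinates.
#' @param exons `GRanges` of the gene's exons, ordered 5'->3' (as stored
#'   in a `gene_set`).
#' @return `GRanges` of the genomic segments (possibly several).
#' @export
transcript_to_genome <- function(tx_start, tx_end, exons) {
  if (tx_end < tx_start) stop("'tx_end' must be >= 'tx_start'")
  w <- GenomicRanges::width(exons)
  if (tx_end > sum(w))
    stop("transcript interval beyond the exon ladder")
  offs <- cumsum(c(0L, w[-length(w)]))
  minus <- as.character(GenomicRanges::strand(exons))[1] == "-"
  segs <- list()
  for (i in seq_along(exons)) {
    lo <- max(tx_start, offs[i] + 1L)
    hi <- min(tx_end, offs[i] + w[i])
    if (lo > hi) next
    within_lo <- lo - offs[i]   # 1-based offset inside the exon, 5'->3'
    within_hi <- hi - offs[i]
    if (minus) {
      gstart <- GenomicRanges::end(exons)[i] - within_hi + 1L
      gend <- GenomicRanges::end(exons)[i] - within_lo + 1L
    } else {
      gstart <- GenomicRanges::start(exons)[i] + within_lo - 1L
      gend <- GenomicRanges::start(exons)[i] + within_hi - 1L
    }
    segs[[length(segs) + 1L]] <- GenomicRanges::GRanges(
      seqnames = GenomicRanges::seqnames(exons)[i],
      IRanges::IRanges(gstart, gend),
      strand = GenomicRanges::strand(exons)[i])
  }
  if (length(segs) == 0L)
    stop("transcript interval outside the exon ladder")
  do.call(c, segs)
}

#' Flag diffs falling inside annotated repeats
#'
#' A diff is in-repeat for a species when its genomic projection (via
#' that species' exon ladder) overlaps at least one base of a repeat
#' feature.  Diffs whose position cannot be projected (beyond the exon
#' ladder, e.g. after an annotation mismatch) are flagged `unmappable`
#' rather than dropped.
#'
#' @param diffs data.frame from [extract_diffs()].
#' @param exons_a,exons_b Exon ladders (`GRanges`, 5'->3') for the two
#'   species; `NULL` to skip a side.
#' @param repeats_a,repeats_b Repeat features for the two species.
#' @return `diffs` with added logical columns `in_repeat_a`,
#'   `in_repeat_b`, `unmappable`.
#' @export
map_diffs_to_repeats <- function(diffs, exons_a, repeats_a,
                                 exons_b, repeats_b) {
  # flattened exon ladder + repeat table: plain-vector arithmetic keeps
  # the per-diff cost negligible on genome-scale cascades
  ladder <- function(exons) {
    w <- GenomicRanges::width(exons)
    list(chrom = as.character(GenomicRanges::seqnames(exons)),
         gstart = GenomicRanges::start(exons),
         gend = GenomicRanges::end(exons),
         minus = as.character(GenomicRanges::strand(exons))[1] == "-",
         tx_lo = cumsum(c(0L, w[-length(w)])) + 1L,
         tx_hi = cumsum(w))
  }
  rep_tab <- function(repeats)
    list(chrom = as.character(GenomicRanges::seqnames(repeats)),
         start = GenomicRanges::start(repeats),
         end = GenomicRanges::end(repeats))
  flag_one <- function(lo, hi, lad, rt) {
    if (hi > max(lad$tx_hi)) return(NA)      # beyond the exon ladder
    hit <- FALSE
    for (e in seq_along(lad$tx_lo)) {
      s <- max(lo, lad$tx_lo[e]); t <- min(hi, lad$tx_hi[e])
      if (s > t) next
      if (lad$minus) {
        glo <- lad$gend[e] - (t - lad$tx_lo[e])
        ghi <- lad$gend[e] - (s - lad$tx_lo[e])
      } else {
        glo <- lad$gstart[e] + (s - lad$tx_lo[e])
        ghi <- lad$gstart[e] + (t - lad$tx_lo[e])
      }
      if (any(rt$chrom == lad$chrom[e] & rt$start <= ghi &
                rt$end >= glo)) { hit <- TRUE; break }
    }
    hit
  }
  flag_side <- function(pos, len, exons, repeats) {
    lad <- ladder(exons); rt <- rep_tab(repeats)
    vapply(seq_along(pos), function(i)
      flag_one(pos[i], pos[i] + len[i] - 1L, lad, rt), logical(1))
  }
  if (nrow(diffs) == 0L) {
    diffs$in_repeat_a <- logical(0)
    diffs$in_repeat_b <- logical(0)
    diffs$unmappable <- logical(0)
    return(diffs)
  }
  # the inserted-against side has no bases of its own: project the
  # 1-bp anchor instead
  len_a <- ifelse(diffs$kind == "insertion_b", 1L, diffs$length)
  len_b <- ifelse(diffs$kind == "insertion_a", 1L, diffs$length)
  pos_a <- ifelse(diffs$kind == "insertion_b", pmax(diffs$pos_a, 1L),
                  diffs$pos_a)
  pos_b <- ifelse(diffs$kind == "insertion_a", pmax(diffs$pos_b, 1L),
                  diffs$pos_b)
  fa <- if (is.null(exons_a)) rep(FALSE, nrow(diffs)) else
    flag_side(pos_a, len_a, exons_a, repeats_a)
  fb <- if (is.null(exons_b)) rep(FALSE, nrow(diffs)) else
    flag_side(pos_b, len_b, exons_b, repeats_b)
  diffs$unmappable <- is.na(fa) | is.na(fb)
  diffs$in_repeat_a <- !is.na(fa) & fa
  diffs$in_repeat_b <- !is.na(fb) & fb
  diffs
}

#' Propagate nucleotide diffs to the amino-acid level
#'
#' Classifies each CDS diff at codon resolution: substitutions are
#' synonymous (no amino-acid change) or non-synonymous; indels with
#' length divisible by 3 are in-frame amino-acid indels; all others are
#' frameshifts.  A pair whose mutated CDS carries an internal stop is
#' flagged `internal_stop` and excluded from downstream cascade counts.
#'
#' @param diffs data.frame from [extract_diffs()] in CDS coordinates.
#' @param cds_a,cds_b CDS sequences (strings or `DNAString`), frame 0.
#' @return A list with `aa_changes` (data.frame: `codon_a`, `codon_b`,
#'   `effect` in `synonymous`/`nonsynonymous`/`aa_indel`/`frameshift`),
#'   `has_aa_change`, and `internal_stop`.
#' @export
propagate_to_protein <- function(diffs, cds_a, cds_b) {
  cds_a <- as.character(cds_a); cds_b <- as.character(cds_b)
  gc_table <- Biostrings::GENETIC_CODE
  codon_at <- function(seq, pos) {
    ci <- (pos - 1L) %/% 3L
    substr(seq, ci * 3L + 1L, ci * 3L + 3L)
  }
  translate1 <- function(codon) {
    if (nchar(codon) < 3L) return(NA_character_)
    aa <- gc_table[codon]
    if (is.na(aa)) "X" else unname(aa)
  }
  internal_stop <- function(seq) {
    n <- nchar(seq) - nchar(seq) %% 3L
    if (n < 6L) return(FALSE)
    codons <- substring(seq, seq(1L, n - 3L, 3L), seq(3L, n - 3L, 3L))
    any(gc_table[codons] == "*", na.rm = TRUE)
  }
  rows <- list()
  for (i in seq_len(nrow(diffs))) {
    d <- diffs[i, ]
    if (d$kind == "substitution") {
      aa_a <- translate1(codon_at(cds_a, d$pos_a))
      aa_b <- translate1(codon_at(cds_b, d$pos_b))
      eff <- if (!is.na(aa_a) && !is.na(aa_b) && aa_a == aa_b)
        "synonymous" else "nonsynonymous"
      rows[[length(rows) + 1L]] <- data.frame(
        codon_a = (d$pos_a - 1L) %/% 3L + 1L,
        codon_b = (d$pos_b - 1L) %/% 3L + 1L,
        effect = eff, stringsAsFactors = FALSE)
    } else {
      eff <- if (d$length %% 3L == 0L) "aa_indel" else "frameshift"
      rows[[length(rows) + 1L]] <- data.frame(
        codon_a = (max(d$pos_a, 1L) - 1L) %/% 3L + 1L,
        codon_b = (max(d$pos_b, 1L) - 1L) %/% 3L + 1L,
        effect = eff, stringsAsFactors = FALSE)
    }
  }
  aa_changes <- if (length(rows) == 0L)
    data.frame(codon_a = integer(), codon_b = integer(),
               effect = character()) else do.call(rbind, rows)
  list(aa_changes = aa_changes,
       has_aa_change = any(aa_changes$effect != "synonymous"),
       internal_stop = internal_stop(cds_a) || internal_stop(cds_b))
}

#' Exonization cascade report
#'
#' Aggregates per-pair flags into the attrition cascade: all pairs ->
#' pairs with repeat-borne indels -> pairs with repeat-borne
#' substitutions -> pairs with amino-acid changes at repeat-borne diffs
#' -> pairs with structure candidates (an external flag column, since
#' structure prediction is out of scope).  Counts are monotone within
#' the repeat-diff branch by construction.
#'
#' @param pair_flags data.frame with one row per orthologue pair and
#'   logical columns `repeat_indel`, `repeat_substitution`, `aa_change`,
#'   `structure_candidate` (optional), `excluded` (optional;
#'   internal-stop pairs).
#' @return Named list of stage counts.
#' @export
exonization_cascade <- function(pair_flags) {
  pf <- pair_flags
  if (is.null(pf$structure_candidate))
    pf$structure_candidate <- rep(FALSE, nrow(pf))
  if (is.null(pf$excluded)) pf$excluded <- rep(FALSE, nrow(pf))
  ok <- !pf$excluded
  list(
    total_pairs = nrow(pf),
    pairs_with_repeat_indels = sum(pf$repeat_indel & ok),
    pairs_with_repeat_substitutions = sum(pf$repeat_substitution & ok),
    pairs_with_aa_changes = sum(pf$aa_change & ok &
                                  (pf$repeat_indel | pf$repeat_substitution)),
    pairs_with_structure_candidates =
      sum(pf$structure_candidate & pf$aa_change & ok &
            (pf$repeat_indel | pf$repeat_substitution)))
}

#' Run the diff cascade for one orthologue pair
#'
#' Convenience wrapper: global DNA alignment of the two CDS, diff
#' extraction, repeat mapping via the exon ladders, and amino-acid
#' propagation.  `repeat_mode` controls whether a diff counts as
#' repeat-borne when it is inside a repeat in either species (default)
#' or must be in both.
#'
#' @param cds_a,cds_b CDS sequences.
#' @param exons_a,exons_b Exon ladders (`GRanges`, 5'->3').
#' @param repeats_a,repeats_b Repeat features.
#' @param repeat_mode `"either"` or `"both"`.
#' @return A list with `diffs`, `protein` (from
#'   [propagate_to_protein()]) and the per-pair flags used by
#'   [exonization_cascade()].
#' @export
exonization_pair <- function(cds_a, cds_b, exons_a, repeats_a,
                             exons_b, repeats_b,
                             repeat_mode = c("either", "both")) {
  repeat_mode <- match.arg(repeat_mode)
  aln <- global_align(cds_a, cds_b, type = "dna")
  diffs <- extract_diffs(aln)
  diffs <- map_diffs_to_repeats(diffs, exons_a, repeats_a,
                                exons_b, repeats_b)
  in_rep <- if (repeat_mode == "either")
    diffs$in_repeat_a | diffs$in_repeat_b
  else diffs$in_repeat_a & diffs$in_repeat_b
  prot <- propagate_to_protein(diffs, cds_a, cds_b)
  aa_eff <- prot$aa_changes$effect
  flags <- data.frame(
    repeat_indel = any(in_rep & diffs$kind != "substitution"),
    repeat_substitution = any(in_rep & diffs$kind == "substitution"),
    aa_change = any(in_rep & aa_eff != "synonymous"),
    excluded = prot$internal_stop)
  list(diffs = diffs, protein = prot, flags = flags)
}
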