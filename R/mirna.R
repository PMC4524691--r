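#' Map pre-miRNA hairpins to a genome
#'
#' Every genomic placement of each pre-miRNA with at most `max_mismatch`
#' substitutions (no indels), both strands.  Multi-locus miRNAs yield
#' one record per placement, sharing the `mirna_id`.
#'
#' @param premirnas Named `DNAStringSet` of pre-miRNA sequences.
#' @param genome Named `DNAStringSet` of chromosomes.
#' @param max_mismatch Maximum substitutions (default 1).
#' @return `GRanges` with metadata `mirna_id` and `copy_index`.
#' @export
map_premirnas <- function(premirnas, genome, max_mismatch = 1) {
  si <- GenomeInfoDb::Seqinfo(seqnames = names(genome),
                              seqlengths = Biostrings::width(genome))
  out <- list()
  for (i in seq_along(premirnas)) {
    pat <- premirnas[[i]]
    for (strand in c("+", "-")) {
      p <- if (strand == "+") pat else Biostrings::reverseComplement(pat)
      m <- Biostrings::vmatchPattern(p, genome,
                                     max.mismatch = max_mismatch,
                                     fixed = TRUE)
      for (ch in names(genome)) {
        r <- m[[ch]]
        if (length(r) == 0L) next
        out[[length(out) + 1L]] <- GenomicRanges::GRanges(
          seqnames = ch, IRanges::IRanges(BiocGenerics::start(r),
                                          BiocGenerics::end(r)),
          strand = strand, mirna_id = names(premirnas)[i],
          seqinfo = si)
      }
    }
  }
  if (length(out) == 0L) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      mirna_id = character(), copy_index = integer())
    return(gr)
  }
  gr <- sort(do.call(c, out), ignore.strand = TRUE)
  idx <- stats::ave(rep(1L, length(gr)), gr$mirna_id, FUN = seq_along)
  gr$copy_index <- as.integer(idx)
  gr
}

#' Repeat overlap of pre-miRNA flanking windows
#'
#' Flags each locus whose +/- `flank_bp` window (pre-miRNA included,
#' clipped at chromosome ends) overlaps at least one repeat, and tests
#' enrichment of flagged loci with the one-sided binomial against the
#' uniform-placement null.
#'
#' @param loci `GRanges` from [map_premirnas()].
#' @param repeats `GRanges` of repeat features.
#' @param assembly `Seqinfo` assembly index.
#' @param flank_bp Flank width each side (default 2000).
#' @return A list with `flagged` (logical per locus), `n_flagged`, and
#'   `p` (enrichment p-value; 1 when there are no repeats).
#' @export
mirna_flank_overlap <- function(loci, repeats, assembly,
                                flank_bp = 2000) {
  if (length(loci) == 0L)
    return(list(flagged = logical(0), n_flagged = 0L, p = 1))
  GenomeInfoDb::seqlevels(loci) <- GenomeInfoDb::seqlevels(assembly)
  GenomeInfoDb::seqinfo(loci) <- assembly
  win <- GenomicRanges::trim(suppressWarnings(loci + flank_bp))
  flagged <- IRanges::overlapsAny(win, repeats, ignore.strand = TRUE)
  merged <- merge_intervals(repeats)
  if (length(merged) == 0L)
    return(list(flagged = flagged, n_flagged = 0L, p = 1))
  p0 <- null_overlap_probability(
    merged, round(stats::median(GenomicRanges::width(win))), assembly)
  list(flagged = flagged, n_flagged = sum(flagged),
       p = enrichment_binomial(sum(flagged), length(flagged), p0))
}

#' miRNA family stem from a miRBase-style identifier
#'
#' `stu-miR156a-5p` -> `miR156`; the species prefix, variant letter and
#' arm suffix are stripped.
#'
#' @param ids Character vector of miRNA identifiers.
#' @return Character vector of family stems.
#' @export
mirna_family <- function(ids) {
  stem <- sub("^[a-zA-Z]{3,4}-", "", ids)
  m <- regmatches(stem, regexpr("^(miR|MIR|let|lin)[0-9]+", stem,
                                ignore.case = FALSE))
  out <- rep(NA_character_, length(ids))
  out[lengths(regmatches(stem, gregexpr("^(miR|MIR|let|lin)[0-9]+",
                                        stem))) > 0] <- m
  out
}

#' Pair orthologous pre-miRNAs across two species
#'
#' A pair requires the same family annotation (name stem) *and* a
#' reciprocal best local-alignment match at identity >=
#' `min_identity`: sharing a name alone is not accepted, since family
#' nomenclature can survive sequence turnover.
#'
#' @param seqs_a,seqs_b Named `DNAStringSet`s of pre-miRNAs (miRBase
#'   naming convention).
#' @param min_identity Identity gate (default 0.7).
#' @return data.frame with `mirna_a`, `mirna_b`, `family`, `identity`.
#' @export
pair_orthologous_mirnas <- function(seqs_a, seqs_b, min_identity = 0.7) {
  fam_a <- mirna_family(names(seqs_a))
  fam_b <- mirna_family(names(seqs_b))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 5,
                                                  mismatch = -4,
                                                  baseOnly = TRUE)
  out <- list()
  for (fam in stats::na.omit(unique(fam_a))) {
    ia <- which(fam_a == fam); ib <- which(fam_b == fam)
    if (length(ia) == 0L || length(ib) == 0L) next
    sc <- matrix(0, length(ia), length(ib))
    idm <- matrix(0, length(ia), length(ib))
    for (k in seq_along(ia)) {
      pa <- Biostrings::pairwiseAlignment(
        rep(Biostrings::DNAStringSet(seqs_a[ia[k]]), length(ib)),
        seqs_b[ib], type = "local", substitutionMatrix = mat,
        gapOpening = 10, gapExtension = 0.5)
      sc[k, ] <- Biostrings::score(pa)
      idm[k, ] <- Biostrings::pid(pa, type = "PID1") / 100
    }
    best_a <- apply(sc, 1, which.max)
    best_b <- apply(sc, 2, which.max)
    for (k in seq_along(ia)) {
      j <- best_a[k]
      if (best_b[j] == k && idm[k, j] >= min_identity)
        out[[length(out) + 1L]] <- data.frame(
          mirna_a = names(seqs_a)[ia[k]],
          mirna_b = names(seqs_b)[ib[j]],
          family = fam, identity = idm[k, j],
          stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(mirna_a = character(), mirna_b = character(),
                      family = character(), identity = numeric()))
  do.call(rbind, out)
}

.masked_matrix <- function() {
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(-4, 5, 5, dimnames = list(letters, letters))
  diag(m) <- 5
  m["N", ] <- -1000
  m[, "N"] <- -1000
  m
}

#' Chained local alignments between two flank sequences
#'
#' Iterative Smith-Waterman between the two flanks (2 kb upstream +
#' pre-miRNA + 2 kb downstream per species): the best local alignment
#' with score >= `min_score` is recorded, its ungapped exact-match runs
#' of at least `min_motif_len` bases become motifs, the aligned spans
#' are masked in both sequences, and the search repeats until no
#' alignment reaches `min_score`.  Masking guarantees termination and
#' pairwise non-overlapping motifs.
#'
#' Scoring is match +5 / mismatch -4 with steep affine gaps (open 25,
#' extend 10): shallow water-style gap extension has a positive
#' expected score on random DNA, which lets unrelated 4 kb flanks chain
#' into arbitrarily large alignments, so gaps are priced high enough
#' that the null stays bounded.  The default `min_score` of 100 (the
#' score of a 20-bp exact match) sits above the empirical null maximum
#' (~86 on random 4.2 kb flank pairs) while a 30-bp relic at 10%
#' divergence still scores 123.
#'
#' @param flank_a,flank_b Flank sequences (strings or `DNAString`).
#' @param min_score Score threshold to keep iterating (default 100).
#' @param min_motif_len Minimum ungapped match run (default 5).
#' @param gap_opening,gap_extension Affine gap prices (default 25, 10).
#' @param max_rounds Safety cap on iterations (default 50).
#' @return data.frame of motifs: `motif_seq`, `pos_a`, `pos_b`
#'   (1-based offsets within the flanks), `length`,
#'   `strand_consistent`.
#' @export
chained_local_alignments <- function(flank_a, flank_b, min_score = 100,
                                     min_motif_len = 5,
                                     gap_opening = 25,
                                     gap_extension = 10,
                                     max_rounds = 50L) {
  a <- as.character(flank_a); b <- as.character(flank_b)
  mat <- .masked_matrix()
  motifs <- list()
  for (round in seq_len(max_rounds)) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b),
      type = "local", substitutionMatrix = mat,
      gapOpening = gap_opening, gapExtension = gap_extension)
    if (Biostrings::score(pa) < min_score) break
    al_a <- as.character(Biostrings::alignedPattern(pa)[[1]])
    al_b <- as.character(Biostrings::alignedSubject(pa)[[1]])
    sa <- BiocGenerics::start(Biostrings::pattern(pa))
    sb <- BiocGenerics::start(Biostrings::subject(pa))
    ea <- BiocGenerics::end(Biostrings::pattern(pa))
    eb <- BiocGenerics::end(Biostrings::subject(pa))
    ca <- strsplit(al_a, "")[[1]]; cb <- strsplit(al_b, "")[[1]]
    off_a <- cumsum(ca != "-"); off_b <- cumsum(cb != "-")
    run_start <- NULL
    match_col <- ca == cb & ca != "-"
    for (i in seq_along(ca)) {
      if (match_col[i] && is.null(run_start)) run_start <- i
      if ((!match_col[i] || i == length(ca)) && !is.null(run_start)) {
        run_end <- if (match_col[i]) i else i - 1L
        len <- run_end - run_start + 1L
        if (len >= min_motif_len)
          motifs[[length(motifs) + 1L]] <- data.frame(
            motif_seq = paste(ca[run_start:run_end], collapse = ""),
            pos_a = sa + off_a[run_start] - 1L,
            pos_b = sb + off_b[run_start] - 1L,
            length = len, strand_consistent = TRUE,
            stringsAsFactors = FALSE)
        run_start <- NULL
      }
    }
    mask <- function(s, from, to)
      paste0(substr(s, 1, from - 1),
             strrep("N", to - from + 1),
             substr(s, to + 1, nchar(s)))
    a <- mask(a, sa, ea)
    b <- mask(b, sb, eb)
  }
  if (length(motifs) == 0L)
    return(data.frame(motif_seq = character(), pos_a = integer(),
                      pos_b = integer(), length = integer(),
                      strand_consistent = logical()))
  res <- do.call(rbind, motifs)
  res[order(res$pos_a), , drop = FALSE]
}

#' Call a repeat footprint from conserved flank motifs
#'
#' Keeps motifs of at least `min_motif_len` bases that overlap a repeat
#' in at least one species (repeat intervals given in flank-local
#' coordinates), classifies the pair by where the repeat support lies
#' (`both`, `a_only`, `b_only`, `none`), and grades strength:
#' `"strong"` requires at least two kept motifs whose relative order
#' and orientation agree in both species, `"candidate"` otherwise.
#' Spacing between motifs is not constrained, only their arrangement.
#'
#' @param motifs data.frame from [chained_local_alignments()].
#' @param repeats_a,repeats_b `IRanges` of repeat segments within the
#'   two flanks (flank-local coordinates).
#' @param min_motif_len Length gate (default 5).
#' @return A list with `motifs` (kept motifs with `in_repeat_a`,
#'   `in_repeat_b`), `class`, `strength` (`NA` when no motif is kept).
#' @export
call_footprints <- function(motifs, repeats_a, repeats_b,
                            min_motif_len = 5) {
  if (nrow(motifs) == 0L)
    return(list(motifs = motifs, class = "none", strength = NA))
  span <- function(pos, len) IRanges::IRanges(pos, width = len)
  motifs$in_repeat_a <- IRanges::overlapsAny(
    span(motifs$pos_a, motifs$length), repeats_a)
  motifs$in_repeat_b <- IRanges::overlapsAny(
    span(motifs$pos_b, motifs$length), repeats_b)
  keep <- motifs$length >= min_motif_len &
    (motifs$in_repeat_a | motifs$in_repeat_b)
  kept <- motifs[keep, , drop = FALSE]
  if (nrow(kept) == 0L)
    return(list(motifs = kept, class = "none", strength = NA))
  cls <- if (any(kept$in_repeat_a) && any(kept$in_repeat_b)) "both"
  else if (any(kept$in_repeat_a)) "a_only"
  else "b_only"
  collinear <- nrow(kept) >= 2 &&
    !is.unsorted(kept$pos_b[order(kept$pos_a)], strictly = TRUE) &&
    all(kept$strand_consistent)
  list(motifs = kept, class = cls,
       strength = if (collinear) "strong" else "candidate")
}
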