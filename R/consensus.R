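#' Reconcile repeat-family annotations from three evidence sources
#'
#' A repeat family library typically carries up to three labels per
#' family: a de novo label (clustering-based), a homology label
#' (library search) and a protein-domain label.  The decision procedure
#' is:
#'
#' * all three labels present and identical -> that label, confidence
#'   `"highest"`;
#' * labels disagree and a domain label is present -> the domain label,
#'   confidence `"domain_based"` (domain evidence dominates);
#' * no domain label -> the label agreed by the de novo and homology
#'   sources (or the single present one), confidence `"agreement_based"`;
#'   if the two disagree, the homology label is used and the record is
#'   flagged for audit;
#' * no usable label -> `"Unknown"`, confidence `"unknown"`.
#'
#' @param labels A data.frame with columns `family_id`, `de_novo`,
#'   `homology`, `domain` (use `NA` for an absent label).
#' @return A data.frame with columns `family_id`, `final_label`,
#'   `confidence`, `evidence` (comma-joined source names used) and
#'   `flagged`.
#' @export
reconcile_labels <- function(labels) {
  stopifnot(all(c("family_id", "de_novo", "homology", "domain") %in%
                  names(labels)))
  one <- function(dn, hom, dom) {
    present <- c(de_novo = dn, homology = hom, domain = dom)
    present <- present[!is.na(present) & nzchar(present)]
    if (length(present) == 0L)
      return(list("Unknown", "unknown", "", FALSE))
    if (length(present) == 3L && length(unique(present)) == 1L)
      return(list(unname(present[1]), "highest",
                  paste(names(present), collapse = ","), FALSE))
    if (!is.na(dom) && nzchar(dom))
      return(list(dom, "domain_based", "domain", FALSE))
    dn_ok <- !is.na(dn) && nzchar(dn)
    hom_ok <- !is.na(hom) && nzchar(hom)
    if (dn_ok && hom_ok) {
      if (dn == hom)
        return(list(dn, "agreement_based", "de_novo,homology", FALSE))
      return(list(hom, "agreement_based", "homology", TRUE))
    }
    lbl <- if (hom_ok) hom else dn
    src <- if (hom_ok) "homology" else "de_novo"
    list(lbl, "agreement_based", src, FALSE)
  }
  rows <- mapply(one, labels$de_novo, labels$homology, labels$domain,
                 SIMPLIFY = FALSE, USE.NAMES = FALSE)
  data.frame(
    family_id = labels$family_id,
    final_label = vapply(rows, `[[`, character(1), 1),
    confidence = vapply(rows, `[[`, character(1), 2),
    evidence = vapply(rows, `[[`, character(1), 3),
    flagged = vapply(rows, `[[`, logical(1), 4),
    stringsAsFactors = FALSE)
}

IUPAC_OK <- strsplit("ACGTRYSWKMBDHVN", "")[[1]]

#' Define a degenerate motif pattern
#'
#' @param name Motif name (e.g. `"A_box"`, `"B_box"`, `"sine_5prime"`).
#' @param pattern IUPAC string.
#' @param max_mismatches Maximum substitutions tolerated (>= 0).
#' @return A `motif_pattern` list.
#' @export
motif_pattern <- function(name, pattern, max_mismatches = 0L) {
  pattern <- toupper(pattern)
  bad <- setdiff(strsplit(pattern, "")[[1]], IUPAC_OK)
  if (length(bad) > 0)
    stop("non-IUPAC symbol(s) in pattern: ", paste(bad, collapse = ""))
  if (max_mismatches < 0) stop("'max_mismatches' must be >= 0")
  structure(list(name = name, pattern = pattern,
                 max_mismatches = as.integer(max_mismatches)),
            class = "motif_pattern")
}

#' Scan a sequence for a degenerate motif on both strands
#'
#' Reports every window matching the IUPAC pattern with at most
#' `max_mismatches` substitutions, on the forward and reverse strand.
#' An `N` in the subject sequence matches nothing (it counts as a
#' mismatch at that position).
#'
#' @param seq A `DNAString` or single character string.
#' @param pattern A [motif_pattern()].
#' @return data.frame with columns `start` (forward-strand coordinate of
#'   the window), `strand` and `mismatches`.
#' @export
scan_iupac <- function(seq, pattern) {
  if (!methods::is(pattern, "motif_pattern"))
    stop("'pattern' must be a motif_pattern")
  subject <- Biostrings::DNAString(as.character(seq))
  pat <- Biostrings::DNAString(pattern$pattern)
  plen <- length(pat)
  if (length(subject) < plen)
    return(data.frame(start = integer(), strand = character(),
                      mismatches = integer()))
  fx <- c(pattern = FALSE, subject = TRUE)
  hits_one <- function(p, strand_lab) {
    m <- Biostrings::matchPattern(p, subject,
                                  max.mismatch = pattern$max_mismatches,
                                  fixed = fx)
    st <- BiocGenerics::start(m)
    if (length(st) == 0L)
      return(data.frame(start = integer(), strand = character(),
                        mismatches = integer()))
    mm <- Biostrings::neditStartingAt(p, subject, starting.at = st,
                                      with.indels = FALSE, fixed = fx)
    data.frame(start = st, strand = strand_lab, mismatches = mm)
  }
  out <- rbind(hits_one(pat, "+"),
               hits_one(Biostrings::reverseComplement(pat), "-"))
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pick the best hit from a BLAST-style hit table
#'
#' Highest score wins; ties break by higher identity, then by
#' lexicographic `subject_id`, so the choice is reproducible.
#'
#' @param hits data.frame with columns `subject_id`, `score`,
#'   `identity` (fraction in `[0,1]`).
#' @return The winning row, or `NULL` for an empty table.
#' @export
best_hit <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0L) return(NULL)
  o <- order(-hits$score, -hits$identity, hits$subject_id)
  hits[o[1], , drop = FALSE]
}

#' Characterize an unknown repeat family through the evidence cascade
#'
#' Families left unlabeled by [reconcile_labels()] are pushed through a
#' fixed cascade: non-coding-RNA hits first (-> `"ncRNA_derived"`), then
#' nucleotide-database hits (-> `"pseudo_gene"`), then diagnostic SINE
#' motifs such as the internal Pol III A-box/B-box promoters
#' (-> `"SINE_like"`).  The first stage with qualifying evidence wins;
#' later evidence never overrides an earlier call.
#'
#' @param family_seq Consensus sequence of the family (string or
#'   `DNAString`); only used by the motif stage.
#' @param ncrna_hits,nt_hits BLAST-style hit tables (may be `NULL` or
#'   empty).
#' @param motif_patterns List of [motif_pattern()]s.
#' @return One of `"ncRNA_derived"`, `"pseudo_gene"`, `"SINE_like"`,
#'   `"Unknown"`, with the supporting evidence as attribute
#'   `"evidence"`.
#' @export
characterize_unknown <- function(family_seq, ncrna_hits = NULL,
                                 nt_hits = NULL,
                                 motif_patterns = list()) {
  bh <- best_hit(ncrna_hits)
  if (!is.null(bh))
    return(structure("ncRNA_derived", evidence = bh$subject_id))
  bh <- best_hit(nt_hits)
  if (!is.null(bh))
    return(structure("pseudo_gene", evidence = bh$subject_id))
  for (p in motif_patterns) {
    if (nrow(scan_iupac(family_seq, p)) > 0)
      return(structure("SINE_like", evidence = p$name))
  }
  structure("Unknown", evidence = NA_character_)
}

#' Match unknown families across two species
#'
#' Reports a pair when the best local alignment between two family
#' consensus sequences reaches `min_identity` over at least `min_cov` of
#' the shorter sequence (and at least `min_len` aligned bases).  One
#' family may match several partners (many-to-one homology is expected
#' for recently duplicated families).
#'
#' @param seqs_a,seqs_b Named `DNAStringSet`s of family consensi.
#' @param min_identity Minimum alignment identity (default 0.8).
#' @param min_cov Minimum aligned fraction of the shorter sequence
#'   (default 0.5).
#' @param min_len Minimum aligned length in bp (default 50).
#' @return data.frame with columns `family_a`, `family_b`, `identity`,
#'   `aligned_length`.
#' @export
match_unknown_families <- function(seqs_a, seqs_b, min_identity = 0.8,
                                   min_cov = 0.5, min_len = 50L) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 5,
                                                  mismatch = -4,
                                                  baseOnly = TRUE)
  out <- list()
  for (i in seq_along(seqs_a)) {
    aln <- Biostrings::pairwiseAlignment(
      rep(Biostrings::DNAStringSet(seqs_a[i]), length(seqs_b)), seqs_b,
      type = "local", substitutionMatrix = mat,
      gapOpening = 10, gapExtension = 4)
    alen <- Biostrings::nchar(aln)
    ident <- Biostrings::pid(aln, type = "PID1") / 100
    shorter <- pmin(Biostrings::width(seqs_a[i]), Biostrings::width(seqs_b))
    keep <- which(ident >= min_identity & alen >= min_len &
                    alen >= min_cov * shorter)
    if (length(keep) > 0)
      out[[length(out) + 1L]] <- data.frame(
        family_a = names(seqs_a)[i],
        family_b = names(seqs_b)[keep],
        identity = ident[keep],
        aligned_length = alen[keep],
        stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(family_a = character(), family_b = character(),
                      identity = numeric(), aligned_length = integer()))
  do.call(rbind, out)
}
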