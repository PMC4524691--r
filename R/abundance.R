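#' RPKM expression measure
#'
#' Reads per kilobase of feature per million mapped reads:
#' `RPKM = 1e9 * count / (library_total * feature_len)`.
#'
#' @param count Mapped read count(s) for the feature.
#' @param feature_len Feature length in bp (> 0).
#' @param library_total Total mapped reads in the library (> 0).
#' @return Numeric RPKM value(s); vectorized.
#' @export
rpkm <- function(count, feature_len, library_total) {
  if (any(feature_len <= 0)) stop("'feature_len' must be positive")
  if (any(library_total <= 0)) stop("'library_total' must be positive")
  1e9 * count / (as.numeric(library_total) * as.numeric(feature_len))
}

#' Average abundance of a repeat family
#'
#' The family average is the sum of member abundances over the full
#' member-by-condition grid divided by
#' `n_members * n_conditions`.  Members expressed in no condition
#' contribute zeros to the grid, so the denominator always reflects the
#' family's full size.
#'
#' @param values Numeric vector of per-member, per-condition abundances
#'   (length `n_members * n_conditions`; missing values count as 0).
#' @param n_members Number of members in the family (> 0).
#' @param n_conditions Number of experimental conditions (> 0).
#' @return The family-average abundance.
#' @export
family_average <- function(values, n_members, n_conditions) {
  if (n_members <= 0 || n_conditions <= 0)
    stop("'n_members' and 'n_conditions' must be positive")
  if (length(values) != n_members * n_conditions)
    stop("'values' must have length n_members * n_conditions ",
         "(pad unexpressed cells with 0)")
  sum(values, na.rm = TRUE) / (n_members * n_conditions)
}

#' Assign microarray probes to genes or repeats
#'
#' A probe is assigned to a gene when its best genomic placement
#' overlaps the gene by more than 90% of the probe length; probes not
#' assignable to a gene are matched to repeats under the same rule;
#' everything else is unassigned.  Gene assignment has strict priority.
#'
#' @param probe_matches `GRanges` of best placements, one per probe,
#'   with metadata `probe_id` and `probe_len`.
#' @param genes `GRanges` of gene spans with `gene_id`.
#' @param repeats `GRanges` of repeat features with `family_id`.
#' @param min_fraction Overlap threshold as a fraction of probe length
#'   (default 0.9, exceeded strictly).
#' @return data.frame with `probe_id`, `target`
#'   (`gene`/`repeat`/`unassigned`), `target_id`, `overlap_fraction`.
#' @export
assign_probes <- function(probe_matches, genes, repeats,
                          min_fraction = 0.9) {
  best_overlap <- function(probes, targets, id_col) {
    frac <- numeric(length(probes))
    id <- rep(NA_character_, length(probes))
    ov <- GenomicRanges::findOverlaps(probes, targets,
                                      ignore.strand = TRUE)
    if (length(ov) > 0) {
      w <- GenomicRanges::width(IRanges::pintersect(
        probes[S4Vectors::queryHits(ov)],
        targets[S4Vectors::subjectHits(ov)], ignore.strand = TRUE))
      f <- w / probe_matches$probe_len[S4Vectors::queryHits(ov)]
      o <- order(S4Vectors::queryHits(ov), -f)
      first <- !duplicated(S4Vectors::queryHits(ov)[o])
      qh <- S4Vectors::queryHits(ov)[o][first]
      frac[qh] <- f[o][first]
      id[qh] <-
        S4Vectors::mcols(targets)[[id_col]][S4Vectors::subjectHits(ov)[o][first]]
    }
    list(frac = frac, id = id)
  }
  g <- best_overlap(probe_matches, genes, "gene_id")
  r <- best_overlap(probe_matches, repeats, "family_id")
  target <- ifelse(g$frac > min_fraction, "gene",
            ifelse(r$frac > min_fraction, "repeat", "unassigned"))
  data.frame(
    probe_id = probe_matches$probe_id,
    target = target,
    target_id = ifelse(target == "gene", g$id,
                ifelse(target == "repeat", r$id, NA_character_)),
    overlap_fraction = ifelse(target == "gene", g$frac,
                       ifelse(target == "repeat", r$frac,
                              pmax(g$frac, r$frac))),
    stringsAsFactors = FALSE)
}

#' Trim adapters and filter small-RNA reads
#'
#' 3' adapter clipping at the leftmost exact occurrence of an adapter
#' prefix of at least `min_overlap` bases (a full internal adapter
#' match also clips); reads shorter than `min_len` after trimming are
#' dropped; reads exactly matching a substring of any ncRNA or
#' transcript sequence are removed as likely degradation products;
#' survivors are deduplicated to unique sequences with counts.
#'
#' @param reads Character vector of read sequences (or `DNAStringSet`).
#' @param adapter 3' adapter sequence.
#' @param ncrna_seqs,transcript_seqs `DNAStringSet`s used for the
#'   degradation filter (either may be `NULL`).
#' @param min_len Minimum retained read length (default 17).
#' @param min_overlap Minimum adapter prefix overlap (default 6).
#' @return data.frame of unique retained reads: `seq`, `count`.
#' @export
process_srna <- function(reads, adapter, ncrna_seqs = NULL,
                         transcript_seqs = NULL, min_len = 17,
                         min_overlap = 6) {
  reads <- as.character(reads)
  trim_one <- function(read) {
    n <- nchar(read)
    la <- nchar(adapter)
    for (i in seq_len(n)) {
      take <- min(la, n - i + 1L)
      if (take < min_overlap) break
      if (substr(read, i, i + take - 1L) ==
          substr(adapter, 1, take))
        return(substr(read, 1, i - 1L))
    }
    read
  }
  trimmed <- vapply(reads, trim_one, character(1), USE.NAMES = FALSE)
  trimmed <- trimmed[nchar(trimmed) >= min_len]
  if (length(trimmed) == 0L)
    return(data.frame(seq = character(), count = integer()))
  uniq <- table(trimmed)
  seqs <- names(uniq)
  is_fragment_of <- function(seqs, refs) {
    if (is.null(refs) || length(refs) == 0L)
      return(rep(FALSE, length(seqs)))
    vapply(seqs, function(s) {
      any(Biostrings::vcountPattern(s, refs, fixed = TRUE) > 0)
    }, logical(1), USE.NAMES = FALSE)
  }
  drop <- is_fragment_of(seqs, ncrna_seqs) |
    is_fragment_of(seqs, transcript_seqs)
  data.frame(seq = seqs[!drop], count = as.integer(uniq[!drop]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Map small-RNA reads to repeat sequences
#'
#' Each unique read is assigned to every repeat it matches with at most
#' `max_mismatch` substitutions (no indels), on either strand; a
#' multi-mapped read counts once per matched family (each-hit
#' counting), or fractionally with `mode = "fractional"`.  The profile
#' reports per-length unique-read counts, per-superfamily mapped
#' counts, and the mapped fraction.
#'
#' @param reads data.frame from [process_srna()] (`seq`, `count`).
#' @param repeat_seqs Named `DNAStringSet` of repeat sequences.
#' @param superfamily Character vector, per repeat sequence.
#' @param max_mismatch Maximum substitutions (default 1).
#' @param mode `"each_hit"` (default) or `"fractional"`.
#' @return A list with `per_length` (data.frame `length`, `n_unique`),
#'   `per_superfamily` (data.frame `superfamily`, `n_mapped`),
#'   `mapped` (logical per read), `mapped_fraction`.
#' @export
map_srna <- function(reads, repeat_seqs, superfamily,
                     max_mismatch = 1, mode = c("each_hit",
                                                "fractional")) {
  mode <- match.arg(mode)
  stopifnot(length(superfamily) == length(repeat_seqs))
  sfs <- sort(unique(superfamily))
  sf_count <- stats::setNames(numeric(length(sfs)), sfs)
  mapped <- logical(nrow(reads))
  for (i in seq_len(nrow(reads))) {
    s <- Biostrings::DNAString(reads$seq[i])
    hit_sf <- character(0)
    for (p in list(s, Biostrings::reverseComplement(s))) {
      cnt <- Biostrings::vcountPattern(p, repeat_seqs,
                                       max.mismatch = max_mismatch,
                                       with.indels = FALSE, fixed = TRUE)
      hit_sf <- c(hit_sf, superfamily[cnt > 0])
    }
    hit_sf <- unique(hit_sf)
    if (length(hit_sf) > 0) {
      mapped[i] <- TRUE
      wgt <- if (mode == "each_hit") 1 else 1 / length(hit_sf)
      sf_count[hit_sf] <- sf_count[hit_sf] + wgt * reads$count[i]
    }
  }
  lens <- nchar(reads$seq)
  per_length <- stats::aggregate(
    list(n_unique = rep(1L, length(lens))), by = list(length = lens),
    FUN = sum)
  list(per_length = per_length,
       per_superfamily = data.frame(superfamily = sfs,
                                    n_mapped = as.numeric(sf_count),
                                    stringsAsFactors = FALSE),
       mapped = mapped,
       mapped_fraction = if (nrow(reads) == 0) 0 else mean(mapped))
}

#' Read a FASTQ file into read sequences
#'
#' Quality strings are parsed but ignored beyond format validation.
#'
#' @param path Path to an (uncompressed) FASTQ file.
#' @return Character vector of read sequences.
#' @export
read_fastq_seqs <- function(path) {
  as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
}
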