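#' Merge overlapping or abutting intervals
#'
#' Collapses a set of intervals into the disjoint, sorted union of their
#' base sets.  Abutting intervals (one ending where the next begins) are
#' merged.  Strand is ignored: coverage and overlap in this package are
#' strand-agnostic throughout; strand is carried only for upstream-window
#' construction and footprint orientation.
#'
#' @param x A `GRanges` (or `IRanges` for single-chromosome work).
#' @return The reduced object, pairwise disjoint and sorted.
#' @examples
#' merge_intervals(GenomicRanges::GRanges("chr1",
#'   IRanges::IRanges(c(1, 6), c(10, 20))))
#' @export
merge_intervals <- function(x) {
  if (methods::is(x, "GRanges"))
    return(GenomicRanges::reduce(x, ignore.strand = TRUE))
  IRanges::reduce(x)
}

#' Count bases covered by a feature set within a region
#'
#' The number of bases in the union of `features` that fall inside
#' `region` (a `GRanges`, or `NULL` for the whole assembly).  Nested and
#' overlapping features are counted once (union, not sum).
#'
#' @param features `GRanges` of features (need not be disjoint).
#' @param region `GRanges` restricting the count, or `NULL` for no
#'   restriction.
#' @return Integer base count.
#' @export
covered_bases <- function(features, region = NULL) {
  merged <- merge_intervals(features)
  if (is.null(region))
    return(sum(as.numeric(GenomicRanges::width(merged))))
  region <- merge_intervals(region)
  hit <- GenomicRanges::intersect(merged, region, ignore.strand = TRUE)
  sum(as.numeric(GenomicRanges::width(hit)))
}

#' Extract feature sequences from an in-memory genome
#'
#' Returns the sequence of each feature; minus-strand features are
#' reverse-complemented.
#'
#' @param genome Named `DNAStringSet` of chromosomes.
#' @param features `GRanges`.
#' @return `DNAStringSet`, one entry per feature.
#' @export
feature_seqs <- function(genome, features) {
  out <- Biostrings::DNAStringSet(vapply(seq_along(features), function(i) {
    ch <- as.character(GenomicRanges::seqnames(features))[i]
    as.character(Biostrings::subseq(genome[[ch]],
                                    GenomicRanges::start(features)[i],
                                    GenomicRanges::end(features)[i]))
  }, character(1)))
  minus <- as.character(GenomicRanges::strand(features)) == "-"
  if (any(minus))
    out[minus] <- Biostrings::reverseComplement(out[minus])
  out
}

#' Strand-aware upstream window of a gene
#'
#' Returns the window of `upstream_bp` bases immediately 5' of each gene
#' start (on the minus strand, immediately 3' of the genomic end), clipped
#' at chromosome edges.  Used for the 5 kb gene-association window and the
#' 2 kb promoter window.
#'
#' @param genes `GRanges` of gene spans with strand and seqlengths set.
#' @param upstream_bp Window width in bp (> 0).
#' @return `GRanges` of upstream windows, zero-width if the gene starts at
#'   a chromosome edge.
#' @export
upstream_flank <- function(genes, upstream_bp) {
  if (upstream_bp <= 0) stop("'upstream_bp' must be positive")
  fl <- suppressWarnings(
    GenomicRanges::flank(genes, width = upstream_bp, start = TRUE))
  GenomicRanges::trim(fl)
}
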