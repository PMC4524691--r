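#' Build an assembly index
#'
#' An assembly index maps chromosome names to their lengths and is the
#' validation backbone for every interval in the package: all coordinates
#' are checked against it at the I/O boundary.
#'
#' @param seqlengths Named integer vector of chromosome lengths (bp).
#' @return A [GenomeInfoDb::Seqinfo] object.
#' @examples
#' asm <- assembly_index(c(chr1 = 1e6, chr2 = 5e5))
#' assembly_total_length(asm)
#' @export
assembly_index <- function(seqlengths) {
  if (is.null(names(seqlengths)) || any(!nzchar(names(seqlengths))))
    stop("'seqlengths' must be a named vector of chromosome lengths")
  if (any(seqlengths <= 0)) stop("chromosome lengths must be positive")
  GenomeInfoDb::Seqinfo(seqnames = names(seqlengths),
                        seqlengths = as.integer(seqlengths))
}

#' @rdname assembly_index
#' @param assembly A `Seqinfo` assembly index.
#' @export
assembly_total_length <- function(assembly) {
  sum(as.numeric(GenomeInfoDb::seqlengths(assembly)))
}

#' @rdname assembly_index
#' @param genome A named `DNAStringSet` (one entry per chromosome).
#' @export
assembly_from_genome <- function(genome) {
  assembly_index(stats::setNames(Biostrings::width(genome), names(genome)))
}

#' Validate a set of features against an assembly index
#'
#' Checks that every feature lies on a known chromosome and within its
#' bounds.  Called by all readers after coordinate conversion.
#'
#' @param gr A `GRanges` of features.
#' @param assembly A `Seqinfo` assembly index.
#' @return `gr`, invisibly, with the assembly attached as its seqinfo.
#' @export
validate_against_assembly <- function(gr, assembly) {
  sl <- GenomeInfoDb::seqlengths(assembly)
  bad_chrom <- !(as.character(GenomicRanges::seqnames(gr)) %in% names(sl))
  if (any(bad_chrom))
    stop("features on chromosomes absent from the assembly: ",
         paste(unique(as.character(GenomicRanges::seqnames(gr))[bad_chrom]),
               collapse = ", "))
  lens <- sl[as.character(GenomicRanges::seqnames(gr))]
  out_of_bounds <- GenomicRanges::start(gr) < 1L |
    GenomicRanges::end(gr) > lens
  if (any(out_of_bounds))
    stop(sum(out_of_bounds), " feature(s) fall outside chromosome bounds")
  GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(assembly)
  GenomeInfoDb::seqinfo(gr) <- assembly
  invisible(gr)
}
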