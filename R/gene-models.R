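#' Gene models: gene spans plus exon structure
#'
#' A gene set is a lightweight container pairing a `GRanges` of gene
#' spans (named by `gene_id`) with a `GRangesList` of exons in the same
#' order.  Exons are stored sorted 5'->3' with respect to the gene's
#' strand; introns are derived as the gene span minus the exons.
#'
#' @param genes `GRanges` of gene spans with a `gene_id` metadata column.
#' @param exons `GRangesList`, one element per gene, exons within the
#'   gene span.
#' @return An object of class `"gene_set"`.
#' @export
gene_set <- function(genes, exons) {
  if (is.null(genes$gene_id)) stop("'genes' must carry a gene_id column")
  if (length(exons) != length(genes))
    stop("'exons' must have one element per gene")
  names(genes) <- genes$gene_id
  names(exons) <- genes$gene_id
  for (i in seq_along(genes)) {
    ex <- exons[[i]]
    if (length(ex) == 0L) next
    if (min(GenomicRanges::start(ex)) < GenomicRanges::start(genes)[i] ||
        max(GenomicRanges::end(ex)) > GenomicRanges::end(genes)[i])
      stop("exons outside gene span for gene ", genes$gene_id[i])
    minus <- as.character(GenomicRanges::strand(genes))[i] == "-"
    o <- order(GenomicRanges::start(ex), decreasing = minus)
    exons[[i]] <- ex[o]
  }
  structure(list(genes = genes, exons = exons), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("gene_set with", length(x$genes), "genes\n")
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$genes)

#' Introns of a gene set
#'
#' Gene span minus exons, per gene.
#'
#' @param gs A `gene_set`.
#' @return `GRangesList` of introns, one element per gene.
#' @export
introns <- function(gs) {
  out <- GenomicRanges::psetdiff(
    BiocGenerics::unstrand(gs$genes),
    GenomicRanges::GRangesList(lapply(gs$exons, BiocGenerics::unstrand)))
  names(out) <- gs$genes$gene_id
  out
}

#' Read gene models from a GFF3 file
#'
#' Assembles one gene model per `gene` record, collecting `exon` records
#' through their `Parent` mRNA (or directly parented exons).  GFF3
#' coordinates are 1-based inclusive and are used as-is (the package
#' convention).
#'
#' @param path Path to a GFF3 file.
#' @param assembly Optional `Seqinfo` for coordinate validation.
#' @return A `gene_set`.
#' @export
read_gff3_genes <- function(path, assembly = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) != 9L))
    stop("malformed GFF3 record at line ", which(lengths(f) != 9L)[1])
  col <- function(i) vapply(f, `[[`, character(1), i)
  type <- col(3)
  attr_field <- function(attrs, key) {
    pat <- paste0("(^|;)", key, "=[^;]*")
    has <- grepl(pat, attrs)
    out <- rep(NA_character_, length(attrs))
    hit <- regmatches(attrs[has], regexpr(pat, attrs[has]))
    out[has] <- sub(paste0("^;?", key, "="), "", hit)
    out
  }
  attrs <- col(9)
  ids <- attr_field(attrs, "ID")
  parents <- attr_field(attrs, "Parent")
  is_gene <- type == "gene"
  if (!any(is_gene)) stop("no gene records in ", path)
  genes <- GenomicRanges::GRanges(
    seqnames = col(1)[is_gene],
    IRanges::IRanges(as.integer(col(4)[is_gene]),
                     as.integer(col(5)[is_gene])),
    strand = col(7)[is_gene],
    gene_id = ids[is_gene])
  # exon -> gene resolution: follow Parent through mRNA if needed
  mrna_parent <- stats::setNames(parents[type == "mRNA"],
                                 ids[type == "mRNA"])
  is_exon <- type == "exon"
  exon_gene <- parents[is_exon]
  via_mrna <- exon_gene %in% names(mrna_parent)
  exon_gene[via_mrna] <- mrna_parent[exon_gene[via_mrna]]
  exon_gr <- GenomicRanges::GRanges(
    seqnames = col(1)[is_exon],
    IRanges::IRanges(as.integer(col(4)[is_exon]),
                     as.integer(col(5)[is_exon])),
    strand = col(7)[is_exon])
  exons <- GenomicRanges::GRangesList(
    lapply(genes$gene_id, function(g) exon_gr[exon_gene == g]))
  if (!is.null(assembly)) {
    genes <- validate_against_assembly(genes, assembly)
    GenomeInfoDb::seqlevels(exon_gr) <- GenomeInfoDb::seqlevels(assembly)
  }
  gene_set(genes, exons)
}

#' Write gene models as GFF3
#'
#' @param gs A `gene_set`.
#' @param path Output path.
#' @export
write_gff3_genes <- function(gs, path) {
  out <- c("##gff-version 3")
  for (i in seq_along(gs$genes)) {
    g <- gs$genes[i]
    gid <- g$gene_id
    st <- as.character(GenomicRanges::strand(g))
    row9 <- function(gr, type, attrs)
      sprintf("%s\trepeatscape\t%s\t%d\t%d\t.\t%s\t.\t%s",
              as.character(GenomicRanges::seqnames(gr)), type,
              GenomicRanges::start(gr), GenomicRanges::end(gr), st, attrs)
    out <- c(out,
             row9(g, "gene", paste0("ID=", gid)),
             row9(g, "mRNA", paste0("ID=", gid, ".t1;Parent=", gid)))
    ex <- gs$exons[[i]]
    if (length(ex) > 0)
      out <- c(out, vapply(seq_along(ex), function(j)
        row9(ex[j], "exon",
             paste0("ID=", gid, ".e", j, ";Parent=", gid, ".t1")),
        character(1)))
  }
  writeLines(out, path)
  invisible(path)
}
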