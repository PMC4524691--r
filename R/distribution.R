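#' Round half up, the presentation convention for percentages
#'
#' Base R's `round()` rounds half to even; printed coverage tables use
#' conventional half-up rounding, so the helper is explicit about it.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Chromosome-wise repeat coverage
#'
#' For every chromosome, the number of bases covered by the merged
#' repeat set, the chromosome length, and the percentage occupied; plus
#' a genome `Total` row that sums base counts before dividing.
#' Coverage is computed on merged intervals so that overlapping
#' annotations are not double-counted.
#'
#' @param repeats `GRanges` of repeat features.
#' @param assembly `Seqinfo` assembly index.
#' @return data.frame with columns `chrom`, `repeat_bp`, `chrom_bp`,
#'   `pct` (raw, unrounded percentage).
#' @export
chromosome_coverage <- function(repeats, assembly) {
  sl <- GenomeInfoDb::seqlengths(assembly)
  merged <- merge_intervals(repeats)
  per_chrom <- vapply(names(sl), function(ch) {
    sum(as.numeric(GenomicRanges::width(
      merged[as.character(GenomicRanges::seqnames(merged)) == ch])))
  }, numeric(1))
  df <- data.frame(chrom = names(sl),
                   repeat_bp = per_chrom,
                   chrom_bp = as.numeric(sl),
                   stringsAsFactors = FALSE)
  total <- data.frame(chrom = "Total",
                      repeat_bp = sum(df$repeat_bp),
                      chrom_bp = sum(df$chrom_bp))
  df <- rbind(df, total)
  df$pct <- 100 * df$repeat_bp / df$chrom_bp
  rownames(df) <- NULL
  df
}

#' Coverage percentage from printed base counts
#'
#' The elementary arithmetic behind a coverage table row: percentage of
#' a region occupied, from the covered and total base counts.
#'
#' @param repeat_bp,total_bp Base counts.
#' @return `100 * repeat_bp / total_bp`.
#' @export
coverage_pct <- function(repeat_bp, total_bp) 100 * repeat_bp / total_bp

#' Partition repeat elements into genic and intergenic
#'
#' An element is *genic* when it overlaps at least one base of any gene
#' span or its upstream window (default 5 kb, the gene-association
#' window); otherwise it is intergenic.  A gene is *associated* when at
#' least one repeat overlaps its span or upstream window.  Raw (not
#' merged) elements are used so the unit of counting is the annotated
#' element.
#'
#' @param repeats `GRanges` of repeat features (metadata column
#'   `superfamily` used for the per-superfamily table when present).
#' @param genes `GRanges` of gene spans (strand and seqlengths set).
#' @param upstream_bp Upstream window width (default 5000).
#' @return A list with `repeat_genic` (logical per element),
#'   `gene_associated` (logical per gene), `per_superfamily`
#'   (data.frame of genic/intergenic counts) and `genic_pct`.
#' @export
partition_genic <- function(repeats, genes, upstream_bp = 5000) {
  up <- upstream_flank(genes, upstream_bp)
  genic_region <- c(BiocGenerics::unstrand(genes[, NULL]),
                    BiocGenerics::unstrand(up[, NULL]))
  repeat_genic <- IRanges::overlapsAny(repeats, genic_region,
                                       ignore.strand = TRUE)
  gene_hit <- IRanges::overlapsAny(genes, repeats, ignore.strand = TRUE) |
    IRanges::overlapsAny(up, repeats, ignore.strand = TRUE)
  sf <- if (!is.null(repeats$superfamily)) repeats$superfamily else
    rep("all", length(repeats))
  tab <- table(superfamily = sf, genic = factor(repeat_genic,
                                                levels = c(TRUE, FALSE)))
  per_sf <- data.frame(superfamily = rownames(tab),
                       n_genic = as.integer(tab[, "TRUE"]),
                       n_intergenic = as.integer(tab[, "FALSE"]),
                       stringsAsFactors = FALSE)
  list(repeat_genic = repeat_genic,
       gene_associated = gene_hit,
       per_superfamily = per_sf,
       genic_pct = 100 * mean(repeat_genic))
}

#' Partition repeats between upstream windows and gene bodies
#'
#' Counts, per superfamily, elements overlapping the upstream window
#' versus the gene body (an element can contribute to both if it
#' overlaps both region types).
#'
#' @inheritParams partition_genic
#' @return data.frame with columns `superfamily`, `n_upstream`,
#'   `n_genebody`.
#' @export
partition_upstream_genebody <- function(repeats, genes,
                                        upstream_bp = 5000) {
  up <- upstream_flank(genes, upstream_bp)
  in_up <- IRanges::overlapsAny(repeats, up, ignore.strand = TRUE)
  in_body <- IRanges::overlapsAny(repeats, genes, ignore.strand = TRUE)
  sf <- if (!is.null(repeats$superfamily)) repeats$superfamily else
    rep("all", length(repeats))
  lev <- sort(unique(sf))
  ag <- function(flag)
    as.integer(tapply(flag, factor(sf, levels = lev), sum, default = 0))
  data.frame(superfamily = lev,
             n_upstream = ag(in_up),
             n_genebody = ag(in_body),
             stringsAsFactors = FALSE)
}

#' Exclusively exonic versus exclusively intronic elements
#'
#' An element is counted *exonic* when all of its gene-overlapping bases
#' fall in exons, *intronic* when all fall in introns; elements
#' straddling an exon-intron junction are counted in neither bucket, and
#' elements not touching any gene are `nongenic`.
#'
#' @param repeats `GRanges` of repeat elements.
#' @param gs A `gene_set` (exon structure required).
#' @return A list with `category` (per-element factor over
#'   `exonic`/`intronic`/`mixed`/`nongenic`) and `counts`.
#' @export
partition_exon_intron <- function(repeats, gs) {
  exon_u <- merge_intervals(unlist(gs$exons, use.names = FALSE))
  intron_u <- merge_intervals(unlist(introns(gs), use.names = FALSE))
  ex_bp <- rep(0, length(repeats))
  in_bp <- rep(0, length(repeats))
  ov_ex <- GenomicRanges::findOverlaps(repeats, exon_u,
                                       ignore.strand = TRUE)
  if (length(ov_ex) > 0) {
    w <- GenomicRanges::width(IRanges::pintersect(
      repeats[S4Vectors::queryHits(ov_ex)],
      exon_u[S4Vectors::subjectHits(ov_ex)], ignore.strand = TRUE))
    ex_bp <- ex_bp + as.numeric(tapply(w, factor(
      S4Vectors::queryHits(ov_ex), levels = seq_along(repeats)), sum,
      default = 0))
  }
  ov_in <- GenomicRanges::findOverlaps(repeats, intron_u,
                                       ignore.strand = TRUE)
  if (length(ov_in) > 0) {
    w <- GenomicRanges::width(IRanges::pintersect(
      repeats[S4Vectors::queryHits(ov_in)],
      intron_u[S4Vectors::subjectHits(ov_in)], ignore.strand = TRUE))
    in_bp <- in_bp + as.numeric(tapply(w, factor(
      S4Vectors::queryHits(ov_in), levels = seq_along(repeats)), sum,
      default = 0))
  }
  category <- ifelse(ex_bp > 0 & in_bp == 0, "exonic",
              ifelse(in_bp > 0 & ex_bp == 0, "intronic",
              ifelse(ex_bp > 0 & in_bp > 0, "mixed", "nongenic")))
  category <- factor(category,
                     levels = c("exonic", "intronic", "mixed", "nongenic"))
  list(category = category, counts = table(category))
}

#' Pearson correlation with its t-test
#'
#' Pearson r between two per-chromosome coverage vectors, with the
#' t-statistic `t = |r| * sqrt(n - 2) / sqrt(1 - r^2)` (reported as a
#' magnitude: negative correlations carry a positive t) and the
#' two-sided p-value from the Student t distribution with `n - 2`
#' degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length `n >= 3` with nonzero
#'   variance.
#' @return A list with `r`, `n`, `t_stat`, `p`.
#' @export
pearson_with_t <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("'x' and 'y' must have equal length")
  if (n < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance")
  r <- stats::cor(x, y)
  list(r = r, n = n, t_stat = t_from_r(r, n),
       p = p_from_r(r, n))
}

#' @rdname pearson_with_t
#' @param r Pearson correlation coefficient.
#' @param n Number of observations.
#' @export
t_from_r <- function(r, n) {
  # |r| at (or within rounding of) 1 is the degenerate perfect-fit limit
  if (abs(r) >= 1 - 1e-15) return(Inf)
  abs(r) * sqrt(n - 2) / sqrt(1 - r^2)
}

#' @rdname pearson_with_t
#' @export
p_from_r <- function(r, n) {
  t <- t_from_r(r, n)
  if (!is.finite(t)) return(0)
  2 * stats::pt(-t, df = n - 2)
}

#' One-sided binomial enrichment test
#'
#' Exact upper-tail probability `P(X >= k)` for `X ~ Binomial(n, p0)`,
#' used for gene-repeat association, TFBS gain and miRNA-flank
#' enrichment screens.
#'
#' @param k_success Observed successes (`0 <= k <= n`).
#' @param n_trials Number of trials.
#' @param p0 Null success probability, strictly inside (0, 1).
#' @return The one-sided p-value.
#' @export
enrichment_binomial <- function(k_success, n_trials, p0) {
  if (p0 <= 0 || p0 >= 1) stop("'p0' must be strictly inside (0, 1)")
  if (k_success < 0 || k_success > n_trials)
    stop("'k_success' must be in [0, n_trials]")
  if (k_success == 0) return(1)
  stats::pbinom(k_success - 1, n_trials, p0, lower.tail = FALSE)
}

#' Null probability that a random interval overlaps a repeat block
#'
#' Closed-form uniform-placement null for the binomial enrichment tests:
#' the probability that an interval of `feature_len` dropped uniformly
#' on the assembly overlaps at least one merged repeat block,
#' `p0 = (covered_bases + n_blocks * feature_len) / total_length`,
#' capped into `(eps, 1 - eps)`.  This closed form tracks the exact
#' placement enumeration to within about one start position per block
#' plus edge clipping.
#'
#' @param merged_repeats `GRanges` of merged repeat blocks.
#' @param feature_len Length of the randomly placed interval (bp).
#' @param assembly `Seqinfo` assembly index.
#' @param eps Cap half-width (default 1e-9).
#' @return `p0` strictly inside (0, 1).
#' @export
null_overlap_probability <- function(merged_repeats, feature_len,
                                     assembly, eps = 1e-9) {
  total <- assembly_total_length(assembly)
  covered <- sum(as.numeric(GenomicRanges::width(merged_repeats)))
  p0 <- (covered + length(merged_repeats) * feature_len) / total
  min(max(p0, eps), 1 - eps)
}

#' Paired t-test for intergenic enrichment of repeat families
#'
#' Two-sided paired t-test on per-superfamily, length-normalized element
#' densities (elements per Mb of region class) in genic versus
#' intergenic space.  Densities are used rather than raw counts because
#' raw counts conflate region size with preference.
#'
#' @param genic_density,intergenic_density Paired numeric vectors, one
#'   entry per superfamily, length >= 3.
#' @return A list with `t`, `p`, `df`.
#' @export
intergenic_enrichment_ttest <- function(genic_density,
                                        intergenic_density) {
  n <- length(genic_density)
  if (length(intergenic_density) != n)
    stop("paired vectors must have equal length")
  if (n < 3) stop("need at least 3 superfamilies")
  d <- intergenic_density - genic_density
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) return(list(t = 0, p = 1, df = n - 1))
    return(list(t = sign(mean(d)) * Inf, p = 0, df = n - 1))
  }
  tt <- stats::t.test(intergenic_density, genic_density, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter))
}
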