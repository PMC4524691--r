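#' Run the full repeat-landscape pipeline on a simulated study
#'
#' Executes every analysis stage in dependency order on a synthetic
#' study generated from `config`: genome simulation, annotation
#' reconciliation, distribution statistics, the exonization cascade,
#' TFBS gain/loss accounting, miRNA footprint detection and abundance
#' accounting.  Each stage writes its tables under `outdir` and
#' contributes to the returned summary; a rerun with the same config
#' produces byte-identical output.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory.
#' @param stages Character vector of stages to run (default all):
#'   `"distribution"`, `"consensus"`, `"exonization"`, `"tfbs"`,
#'   `"mirna"`, `"abundance"`.
#' @return The summary list, invisibly; also written to
#'   `outdir/summary.json`.
#' @export
run_pipeline <- function(config, outdir,
                         stages = c("distribution", "consensus",
                                    "exonization", "tfbs", "mirna",
                                    "abundance")) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name)
    utils::write.table(df, file.path(outdir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  summary <- list(seed = config$seed)

  sim <- simulate_genome(config)
  ort <- plant_orthologs(config, sim)
  mir <- plant_mirna_footprints(config, sim)
  rds <- simulate_reads(config, sim)
  write_sim(sim, file.path(outdir, "inputs"))

  if ("distribution" %in% stages) {
    cov <- chromosome_coverage(sim$repeats, sim$assembly)
    cov$pct <- round_half_up(cov$pct, 2)
    tsv(cov, "chromosome_coverage.tsv")
    summary$genome_repeat_pct <- cov$pct[cov$chrom == "Total"]

    chroms <- GenomeInfoDb::seqnames(sim$assembly)
    exon_u <- merge_intervals(unlist(sim$genes$exons, use.names = FALSE))
    gene_pct <- vapply(chroms, function(ch) {
      region <- GenomicRanges::GRanges(ch, IRanges::IRanges(
        1, GenomeInfoDb::seqlengths(sim$assembly)[[ch]]))
      100 * covered_bases(exon_u, region) /
        GenomeInfoDb::seqlengths(sim$assembly)[[ch]]
    }, numeric(1))
    sf_rows <- lapply(sort(unique(sim$repeats$superfamily)),
                      function(sf) {
      sub <- sim$repeats[sim$repeats$superfamily == sf]
      sf_pct <- vapply(chroms, function(ch) {
        region <- GenomicRanges::GRanges(ch, IRanges::IRanges(
          1, GenomeInfoDb::seqlengths(sim$assembly)[[ch]]))
        100 * covered_bases(sub, region) /
          GenomeInfoDb::seqlengths(sim$assembly)[[ch]]
      }, numeric(1))
      ct <- pearson_with_t(sf_pct, gene_pct)
      data.frame(superfamily = sf, pcc = ct$r, t_stat = ct$t_stat,
                 p_value = ct$p, stringsAsFactors = FALSE)
    })
    tsv(do.call(rbind, sf_rows), "repeat_gene_correlation.tsv")

    part <- partition_genic(sim$repeats, sim$genes$genes)
    tsv(part$per_superfamily, "partition_genic.tsv")
    summary$genic_repeat_pct <- part$genic_pct
    summary$pct_genes_repeat_associated <- 100 * mean(part$gene_associated)
    merged <- merge_intervals(sim$repeats)
    p0 <- null_overlap_probability(
      merged, round(stats::median(GenomicRanges::width(sim$genes$genes))),
      sim$assembly)
    summary$gene_association_binomial_p <- enrichment_binomial(
      sum(part$gene_associated), length(part$gene_associated), p0)

    ei <- partition_exon_intron(sim$repeats, sim$genes)
    tsv(as.data.frame(ei$counts), "partition_exon_intron.tsv")

    up <- upstream_flank(sim$genes$genes, 5000)
    genic_region <- merge_intervals(c(sim$genes$genes[, NULL],
                                      BiocGenerics::unstrand(up[, NULL])))
    genic_mb <- sum(as.numeric(GenomicRanges::width(genic_region))) / 1e6
    inter_mb <- assembly_total_length(sim$assembly) / 1e6 - genic_mb
    psf <- part$per_superfamily
    tt <- intergenic_enrichment_ttest(psf$n_genic / genic_mb,
                                      psf$n_intergenic / inter_mb)
    summary$intergenic_ttest_p <- tt$p
  }

  if ("consensus" %in% stages) {
    fam <- config$families
    n <- nrow(fam)
    dn <- fam$superfamily
    hom <- fam$superfamily
    dom <- ifelse(seq_len(n) %% 2L == 0L, fam$superfamily,
                  NA_character_)
    hom[seq_len(n) %% 3L == 0L] <- NA_character_   # homology misses some
    labels <- data.frame(family_id = fam$family_id, de_novo = dn,
                         homology = hom, domain = dom,
                         stringsAsFactors = FALSE)
    dec <- reconcile_labels(labels)
    tsv(dec, "consensus_decisions.tsv")
    summary$n_highest_confidence <- sum(dec$confidence == "highest")
  }

  if ("exonization" %in% stages) {
    gs <- sim$genes
    empty_rep <- GenomicRanges::GRanges()
    flags <- lapply(seq_len(nrow(ort$pairs)), function(i) {
      exonization_pair(ort$cds_a[i], ort$cds_b[i],
                       gs$exons[[i]], ort$repeats_a,
                       NULL, empty_rep)$flags
    })
    flags <- do.call(rbind, flags)
    casc <- exonization_cascade(flags)
    jsonlite::write_json(casc, file.path(outdir, "exonization_cascade.json"),
                         auto_unbox = TRUE)
    summary$exonization_rate_recovered <-
      casc$pairs_with_repeat_indels / casc$total_pairs
    summary$exonization_rate_planted <- mean(ort$pairs$planted_indel)
  }

  if ("tfbs" %in% stages) {
    set.seed(config$seed + 4L)
    genes <- sim$genes$genes
    win <- upstream_flank(genes, 2000)
    rep_in_win <- IRanges::pintersect(
      IRanges::findOverlapPairs(win, merge_intervals(sim$repeats),
                                ignore.strand = TRUE))
    make_hits <- function(mean_sites, tag) {
      rows <- list()
      for (g in seq_along(genes)) {
        w <- win[g]
        if (GenomicRanges::width(w) < 10) next
        segs <- rep_in_win[IRanges::overlapsAny(rep_in_win, w)]
        for (tf in names(config$tfbs_patterns)) {
          k <- stats::rpois(1, mean_sites)
          if (k == 0) next
          site_w <- nchar(config$tfbs_patterns[[tf]])
          for (s in seq_len(k)) {
            in_rep <- length(segs) > 0 &&
              stats::runif(1) < config$tfbs_repeat_fraction
            if (in_rep) {
              seg <- segs[sample(length(segs), 1)]
              lo <- GenomicRanges::start(seg)
              hi <- max(lo, GenomicRanges::end(seg) - site_w + 1L)
            } else {
              lo <- GenomicRanges::start(w)
              hi <- max(lo, GenomicRanges::end(w) - site_w + 1L)
            }
            st <- if (hi > lo) sample(lo:hi, 1) else lo
            rows[[length(rows) + 1L]] <- data.frame(
              tf_name = tf, gene_id = genes$gene_id[g],
              chrom = as.character(GenomicRanges::seqnames(w)),
              start = st, end = st + site_w - 1L,
              score = round(stats::runif(1, 5, 15), 3),
              stringsAsFactors = FALSE)
          }
        }
      }
      do.call(rbind, rows)
    }
    hits_a <- make_hits(config$tfbs_per_window, "a")
    hits_b <- make_hits(config$tfbs_per_window * 0.7, "b")
    counts_a <- count_tfbs(hits_a, genes)
    counts_b <- count_tfbs(hits_b, genes)
    pairs <- data.frame(gene_a = genes$gene_id, gene_b = genes$gene_id)
    gl <- tfbs_gain_loss(counts_a, counts_b, pairs, hits_a, hits_b)
    p0 <- tfbs_window_repeat_fraction(genes, sim$repeats)
    att <- attribute_gains_to_repeats(gl, sim$repeats, sim$repeats,
                                      p0 = p0)
    tsv(att$summary, "tfbs_gain_summary.tsv")
    summary$tfbs_window_repeat_fraction <- p0
    summary$tfbs_mean_pct_repeat <- mean(att$summary$pct_repeat)
  }

  if ("mirna" %in% stages) {
    loci <- map_premirnas(mir$premirnas_a, mir$genome, max_mismatch = 0)
    fo <- mirna_flank_overlap(loci, sim$repeats, sim$assembly,
                              config$mirna_flank_bp)
    mp <- pair_orthologous_mirnas(mir$premirnas_a, mir$premirnas_b)
    calls <- lapply(seq_len(nrow(mir$pairs)), function(i) {
      motifs <- chained_local_alignments(mir$flanks_a[i],
                                         mir$flanks_b[i])
      # the conserved hairpin core is expected and uninformative;
      # footprint evidence comes from repeat-overlapping flank motifs
      call_footprints(motifs, mir$repeats_a[[i]], mir$repeats_b[[i]])
    })
    call_df <- data.frame(
      mirna_a = mir$pairs$mirna_a, mirna_b = mir$pairs$mirna_b,
      truth_class = mir$pairs$class,
      called_class = vapply(calls, `[[`, character(1), "class"),
      strength = vapply(calls, function(x)
        if (is.na(x$strength[1])) "none" else x$strength, character(1)),
      stringsAsFactors = FALSE)
    tsv(call_df, "mirna_footprints.tsv")
    tsv(as.data.frame(loci), "mirna_loci.tsv")
    pos <- call_df$truth_class != "none"
    summary$footprint_sensitivity <-
      if (any(pos)) mean(call_df$called_class[pos] ==
                           call_df$truth_class[pos]) else NA
    summary$footprint_specificity <-
      if (any(!pos)) mean(call_df$called_class[!pos] == "none") else NA
    summary$n_mirna_loci <- length(loci)
    summary$mirna_flank_enrichment_p <- fo$p
    summary$n_orthologous_mirna_pairs <- nrow(mp)
  }

  if ("abundance" %in% stages) {
    lib_totals <- colSums(rds$counts)
    lib_totals[lib_totals == 0] <- 1
    rp <- sweep(sweep(rds$counts, 2, lib_totals, "/"), 1,
                GenomicRanges::width(rds$count_features), "/") * 1e9
    fam_ids <- rds$count_features$family_id
    fam_avg <- vapply(sort(unique(fam_ids)), function(f) {
      vals <- rp[fam_ids == f, , drop = FALSE]
      family_average(as.numeric(vals), nrow(vals), ncol(vals))
    }, numeric(1))
    tsv(data.frame(family_id = names(fam_avg),
                   average_abundance = as.numeric(fam_avg)),
        "family_abundance.tsv")
    summary$top_family_by_abundance <- names(which.max(fam_avg))

    pa <- assign_probes(rds$probe_matches, sim$genes$genes, sim$repeats)
    tsv(pa, "probe_assignment.tsv")
    summary$probe_assignment_accuracy <-
      mean(pa$target == rds$probe_truth)

    reads <- process_srna(rds$srna_reads, config$srna_adapter)
    rep_seqs <- feature_seqs(sim$genome,
                             BiocGenerics::unstrand(sim$repeats))
    profile <- map_srna(reads, rep_seqs, sim$repeats$superfamily)
    tsv(profile$per_length, "srna_length_histogram.tsv")
    tsv(profile$per_superfamily, "srna_superfamily.tsv")
    summary$srna_modal_length <- profile$per_length$length[
      which.max(profile$per_length$n_unique)]
    summary$srna_mapped_fraction <- profile$mapped_fraction
  }

  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}
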