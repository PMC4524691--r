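#' Simulation configuration
#'
#' Bundles every parameter of the synthetic study: a multi-chromosome
#' genome with planted repeat families (per-copy divergence), genes
#' with exon structure, orthologue pairs carrying repeat-borne indels
#' at rate `exonization_q`, upstream TFBS (a configurable fraction
#' inside repeats), multi-locus pre-miRNAs with eroded-repeat
#' footprints, negative-binomially distributed expression counts, and
#' 24-nt-biased small-RNA reads.  The seed fully determines all
#' output.
#'
#' @param seed Integer seed.
#' @param n_chroms,chrom_len Genome shape (default 3 x 200 kb).
#' @param families data.frame with `family_id`, `superfamily`,
#'   `consensus_len`, `n_copies`, `divergence`.
#' @param n_genes Number of genes (and orthologue pairs).
#' @param exonization_q Fraction of pairs receiving an in-frame indel
#'   inside an exonized repeat segment (default 0.2).
#' @param ortholog_divergence Per-base substitution rate between
#'   orthologous CDS (default 0.05).
#' @param n_frameshift_pairs Pairs receiving a frame-shifting indel
#'   instead (default 0).
#' @param tfbs_patterns Named character vector of IUPAC site motifs.
#' @param tfbs_per_window Mean planted sites per promoter window.
#' @param tfbs_repeat_fraction Fraction of planted sites placed inside
#'   repeat-overlapping window sequence.
#' @param mirna_classes Named integer vector: footprint pairs per class
#'   (`both`, `a_only`, `b_only`, `none`).
#' @param mirna_relic_len Conserved relic length (default 30).
#' @param mirna_core_len Pre-miRNA length (default 120).
#' @param mirna_flank_bp Flank width each side (default 2000).
#' @param n_multilocus_mirnas,multilocus_copies Hairpins inserted at
#'   several genomic loci.
#' @param nb_mean,nb_size Named per-family negative-binomial mean and
#'   common dispersion for expression counts.
#' @param n_conditions Expression conditions (default 5).
#' @param srna_n_reads Small-RNA reads to draw (default 4000).
#' @param srna_len_probs Named probability vector over read lengths,
#'   peaked at 24 nt.
#' @param srna_adapter 3' adapter appended to raw reads.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 3L,
                       chrom_len = 200000L,
                       families = default_families(),
                       n_genes = 200L,
                       exonization_q = 0.2,
                       ortholog_divergence = 0.05,
                       n_frameshift_pairs = 0L,
                       tfbs_patterns = c(Ibox = "GATAAG",
                                         L1_box = "TAAATGYA",
                                         Hexamer = "CCGTCG"),
                       tfbs_per_window = 3,
                       tfbs_repeat_fraction = 0.4,
                       mirna_classes = c(both = 8L, a_only = 4L,
                                         b_only = 2L, none = 6L),
                       mirna_relic_len = 30L,
                       mirna_core_len = 120L,
                       mirna_flank_bp = 2000L,
                       n_multilocus_mirnas = 5L,
                       multilocus_copies = 3L,
                       nb_mean = NULL,
                       nb_size = 2,
                       n_conditions = 5L,
                       srna_n_reads = 4000L,
                       srna_len_probs = default_srna_lengths(),
                       srna_adapter = "TGGAATTCTCGGGTGCCAAGG") {
  stopifnot(exonization_q >= 0, exonization_q <= 1,
            tfbs_repeat_fraction >= 0, tfbs_repeat_fraction <= 1)
  if (is.null(nb_mean)) {
    nb_mean <- stats::setNames(c(50, 20, 10, 80, 5, 30)[
      seq_len(nrow(families))], families$family_id)
  }
  structure(as.list(environment()), class = "sim_config")
}

#' @rdname sim_config
#' @export
default_families <- function() {
  data.frame(
    family_id = c("rnd-1_family-1", "rnd-1_family-2", "rnd-2_family-3",
                  "rnd-2_family-4", "rnd-3_family-5", "rnd-3_family-6"),
    superfamily = c("LTR/Gypsy", "LTR/Copia", "LINE/L1",
                    "DNA/TcMar-Stowaway", "DNA/hAT-Ac", "SINE/tRNA"),
    consensus_len = c(400L, 300L, 250L, 180L, 200L, 120L),
    n_copies = c(180L, 120L, 80L, 100L, 60L, 60L),
    divergence = c(0.12, 0.15, 0.18, 0.08, 0.10, 0.05),
    stringsAsFactors = FALSE)
}

#' @rdname sim_config
#' @export
default_srna_lengths <- function() {
  lens <- 17:30
  p <- stats::dnorm(lens, mean = 24, sd = 2)
  p[lens == 24] <- p[lens == 24] * 2   # sharpen the canonical 24-nt peak
  stats::setNames(p / sum(p), lens)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Mutate a sequence at a target divergence
#'
#' Applies `round(divergence * len)` mutation events: a 9:1 mix of
#' substitutions and short (1-3 bp) indels, the conventional decay
#' model for transposable-element copies.
#'
#' @param seq Character sequence.
#' @param divergence Events per base in `[0, 1]`.
#' @param indel_frac Fraction of events that are indels (default 0.1).
#' @return Mutated character sequence.
#' @export
mutate_seq <- function(seq, divergence, indel_frac = 0.1) {
  chars <- strsplit(seq, "")[[1]]
  n_events <- round(divergence * length(chars))
  if (n_events == 0) return(seq)
  pos <- sample(length(chars), min(n_events, length(chars)))
  is_indel <- stats::runif(length(pos)) < indel_frac
  bases <- c("A", "C", "G", "T")
  for (i in seq_along(pos)) {
    p <- pos[i]
    if (p > length(chars)) next
    if (!is_indel[i]) {
      chars[p] <- sample(setdiff(bases, chars[p]), 1)
    } else if (stats::runif(1) < 0.5) {
      k <- sample(1:3, 1)
      chars <- append(chars, sample(bases, k, replace = TRUE), after = p)
    } else {
      k <- min(sample(1:3, 1), length(chars) - p)
      if (k > 0) chars <- chars[-(p + seq_len(k) - 1L)]
    }
  }
  paste(chars, collapse = "")
}

#' Simulate a genome with planted repeats and genes
#'
#' Background sequence is i.i.d. uniform ACGT.  Each repeat family gets
#' a random consensus; copies are mutated at the family divergence and
#' written into the background at uniform positions (copies may nest,
#' as real elements do).  Genes are placed without overlapping each
#' other, with 1-4 exons; gene placement is independent of repeats, so
#' genic repeats arise naturally.  Every planted feature is recorded in
#' the truth manifest.
#'
#' @param config A [sim_config()].
#' @return A list with `genome` (`DNAStringSet`), `assembly`
#'   (`Seqinfo`), `repeats` (`GRanges`), `genes` (`gene_set`),
#'   `consensi` (`DNAStringSet`) and `truth`.
#' @export
simulate_genome <- function(config) {
  set.seed(config$seed)
  chrom_names <- paste0("chr", seq_len(config$n_chroms))
  chroms <- lapply(chrom_names, function(ch)
    strsplit(random_dna(config$chrom_len), "")[[1]])
  names(chroms) <- chrom_names
  fam <- config$families
  total_repeat_bp <- sum(fam$consensus_len * fam$n_copies)
  if (total_repeat_bp > 0.8 * config$n_chroms * config$chrom_len)
    stop("requested repeat content exceeds genome capacity")
  consensi <- stats::setNames(
    vapply(fam$consensus_len, random_dna, character(1)), fam$family_id)
  rep_rows <- list()
  for (f in seq_len(nrow(fam))) {
    for (k in seq_len(fam$n_copies[f])) {
      copy <- mutate_seq(consensi[[fam$family_id[f]]], fam$divergence[f])
      w <- nchar(copy)
      ch <- sample(chrom_names, 1)
      start <- sample(config$chrom_len - w, 1)
      chroms[[ch]][start:(start + w - 1L)] <- strsplit(copy, "")[[1]]
      rep_rows[[length(rep_rows) + 1L]] <- data.frame(
        chrom = ch, start = start, end = start + w - 1L,
        strand = sample(c("+", "-"), 1),
        family_id = fam$family_id[f], superfamily = fam$superfamily[f],
        divergence = fam$divergence[f], stringsAsFactors = FALSE)
    }
  }
  rp <- do.call(rbind, rep_rows)
  assembly <- assembly_index(stats::setNames(
    rep(config$chrom_len, config$n_chroms), chrom_names))
  repeats <- GenomicRanges::GRanges(
    rp$chrom, IRanges::IRanges(rp$start, rp$end), strand = rp$strand,
    family_id = rp$family_id, superfamily = rp$superfamily,
    class = repeat_class(rp$superfamily), source = "de_novo",
    divergence = rp$divergence, score = 0,
    seqinfo = assembly)
  # genes: non-overlapping spans, round-robin across chromosomes
  genes_per_chrom <- table(factor(
    rep(chrom_names, length.out = config$n_genes), levels = chrom_names))
  gene_rows <- list()
  exon_list <- list()
  gid <- 0L
  for (ch in chrom_names) {
    n_here <- genes_per_chrom[[ch]]
    if (n_here == 0L) next
    slot_w <- config$chrom_len %/% n_here
    for (j in seq_len(n_here)) {
      gid <- gid + 1L
      span_w <- sample(900:min(3000, slot_w - 100), 1)
      lo <- (j - 1L) * slot_w + sample(max(1, slot_w - span_w - 50), 1)
      hi <- lo + span_w - 1L
      strand <- sample(c("+", "-"), 1)
      n_ex <- sample(1:4, 1)
      cuts <- sort(sample(seq(lo + 50, hi - 50, by = 10),
                          2L * n_ex - 2L))
      bounds <- matrix(c(lo, cuts, hi), ncol = 2, byrow = TRUE)
      id <- sprintf("gene%04d", gid)
      gene_rows[[gid]] <- data.frame(
        chrom = ch, start = lo, end = hi, strand = strand,
        gene_id = id, stringsAsFactors = FALSE)
      exon_list[[gid]] <- GenomicRanges::GRanges(
        ch, IRanges::IRanges(bounds[, 1], bounds[, 2]), strand = strand,
        seqinfo = assembly)
    }
  }
  gdf <- do.call(rbind, gene_rows)
  genes_gr <- GenomicRanges::GRanges(
    gdf$chrom, IRanges::IRanges(gdf$start, gdf$end),
    strand = gdf$strand, gene_id = gdf$gene_id, seqinfo = assembly)
  gs <- gene_set(genes_gr, GenomicRanges::GRangesList(exon_list))
  genome <- Biostrings::DNAStringSet(
    vapply(chroms, paste, character(1), collapse = ""))
  list(genome = genome, assembly = assembly, repeats = repeats,
       genes = gs, consensi = Biostrings::DNAStringSet(consensi),
       truth = list(repeats = repeats, genes = gs, config = config))
}

random_cds <- function(n_codons) {
  codons <- character(n_codons)
  for (i in seq_len(n_codons)) {
    repeat {
      c3 <- random_dna(3)
      if (!(c3 %in% c("TAA", "TAG", "TGA"))) break
    }
    codons[i] <- c3
  }
  paste0("ATG", paste(codons[-1], collapse = ""))
}

mutate_cds <- function(cds, rate) {
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  bases <- c("A", "C", "G", "T")
  n_sub <- stats::rbinom(1, nchar(cds), rate)
  pos <- sample(nchar(cds), min(n_sub, nchar(cds)))
  for (p in pos) {
    ci <- (p - 1L) %/% 3L + 1L
    if (ci == 1L) next                      # keep the start codon
    old <- codons[ci]
    off <- (p - 1L) %% 3L + 1L
    repeat {
      newb <- sample(setdiff(bases, substr(old, off, off)), 1)
      cand <- old
      substr(cand, off, off) <- newb
      if (!(cand %in% c("TAA", "TAG", "TGA"))) { codons[ci] <- cand; break }
    }
  }
  paste(codons, collapse = "")
}

#' Plant an orthologous gene set with repeat-borne indels
#'
#' Builds, for every gene of the simulated genome, a clean CDS pair:
#' species A gets a random stop-free CDS matching its exon-ladder
#' length, species B a copy diverged at `ortholog_divergence`
#' (substitutions only, stop codons avoided).  A fraction
#' `exonization_q` of pairs additionally receives one in-frame 3-bp
#' deletion in species B at a CDS position whose genomic projection is
#' covered by a planted *exonized repeat* segment (appended to the
#' species-A repeat annotation); optionally, `n_frameshift_pairs`
#' receive a 2-bp deletion instead.  The truth manifest records which
#' pairs carry which event.
#'
#' @param config A [sim_config()].
#' @param sim Output of [simulate_genome()].
#' @return A list with `cds_a`, `cds_b` (named character vectors),
#'   `proteins_a`, `proteins_b` (`AAStringSet`s), `repeats_a`
#'   (species-A repeats including the exonized segments), `pairs`
#'   (data.frame with truth flags `planted_indel`,
#'   `planted_frameshift`).
#' @export
plant_orthologs <- function(config, sim) {
  set.seed(config$seed + 1L)
  gs <- sim$genes
  n <- length(gs)
  ids <- gs$genes$gene_id
  tx_len <- vapply(gs$exons, function(e)
    sum(GenomicRanges::width(e)), numeric(1))
  n_codons <- pmax(30L, as.integer(tx_len) %/% 3L)
  flagged <- sample(n, round(config$exonization_q * n))
  fs_pairs <- if (config$n_frameshift_pairs > 0)
    sample(setdiff(seq_len(n), flagged), config$n_frameshift_pairs)
  else integer(0)
  cds_a <- character(n); cds_b <- character(n)
  exo_rows <- list()
  for (i in seq_len(n)) {
    a <- random_cds(n_codons[i])
    b <- mutate_cds(a, config$ortholog_divergence)
    del_len <- if (i %in% flagged) 3L else if (i %in% fs_pairs) 2L else 0L
    if (del_len > 0L) {
      cds_len <- nchar(a)
      usable <- min(cds_len, tx_len[i])
      p <- (sample((usable %/% 3L) - 10L, 1) + 4L) * 3L + 1L
      b <- paste0(substr(b, 1, p - 1L), substr(b, p + del_len, nchar(b)))
      seg_lo <- max(1L, p - 30L)
      seg_hi <- min(usable, p + 30L)
      segs <- transcript_to_genome(seg_lo, seg_hi, gs$exons[[i]])
      sf <- sample(config$families$superfamily, 1)
      for (s in seq_along(segs)) {
        exo_rows[[length(exo_rows) + 1L]] <- GenomicRanges::GRanges(
          GenomicRanges::seqnames(segs)[s],
          IRanges::IRanges(GenomicRanges::start(segs)[s],
                           GenomicRanges::end(segs)[s]),
          strand = "+",
          family_id = paste0("exonized-", ids[i]), superfamily = sf,
          class = repeat_class(sf), source = "de_novo",
          divergence = 0.3, score = 0,
          seqinfo = sim$assembly)
      }
    }
    cds_a[i] <- a; cds_b[i] <- b
  }
  names(cds_a) <- ids
  names(cds_b) <- sub("^gene", "geneB_", ids)
  repeats_a <- if (length(exo_rows) > 0)
    c(sim$repeats, do.call(c, exo_rows)) else sim$repeats
  translate_set <- function(x) {
    x <- substr(x, 1, nchar(x) - nchar(x) %% 3L)  # frameshifted copies
    aa <- Biostrings::translate(Biostrings::DNAStringSet(x),
                                if.fuzzy.codon = "X")
    Biostrings::AAStringSet(sub("\\*$", "", as.character(aa)))
  }
  pairs <- data.frame(
    gene_a = names(cds_a), gene_b = names(cds_b),
    planted_indel = seq_len(n) %in% flagged,
    planted_frameshift = seq_len(n) %in% fs_pairs,
    stringsAsFactors = FALSE)
  list(cds_a = cds_a, cds_b = cds_b,
       proteins_a = translate_set(cds_a),
       proteins_b = translate_set(cds_b),
       repeats_a = repeats_a, pairs = pairs)
}

#' Plant orthologous pre-miRNAs with eroded-repeat footprints
#'
#' For each configured pair, builds a flank bundle per species (2 kb
#' upstream + pre-miRNA core + 2 kb downstream).  The core is conserved
#' between species; the rest of each flank is independent random
#' sequence, except that footprint-positive pairs share one
#' `mirna_relic_len`-bp relic and one two-thirds-length relic at
#' consistent relative positions (collinear, so the footprint grades
#' strong).  Repeat annotation over the relics is retained in species
#' A, B or both according to the pair's class.  Separately, hairpins
#' are inserted into the genome at one or several loci for the mapping
#' analysis.
#'
#' @param config A [sim_config()].
#' @param sim Output of [simulate_genome()] (its genome is modified to
#'   carry the inserted hairpin loci).
#' @return A list with `pairs` (data.frame: ids, class), `flanks_a`,
#'   `flanks_b` (character), `repeats_a`, `repeats_b` (lists of
#'   `IRanges` in flank coordinates), `relic_truth` (data.frame of
#'   planted relic offsets), `premirnas_a`, `premirnas_b`
#'   (`DNAStringSet`), `genome` (with hairpins), `loci_truth`.
#' @export
plant_mirna_footprints <- function(config, sim) {
  set.seed(config$seed + 2L)
  classes <- rep(names(config$mirna_classes), config$mirna_classes)
  n <- length(classes)
  fb <- config$mirna_flank_bp
  core_len <- config$mirna_core_len
  rl <- config$mirna_relic_len
  flanks_a <- character(n); flanks_b <- character(n)
  reps_a <- vector("list", n); reps_b <- vector("list", n)
  relic_rows <- list()
  cores <- character(n)
  for (i in seq_len(n)) {
    core <- random_dna(core_len)
    cores[i] <- core
    up_a <- random_dna(fb); dn_a <- random_dna(fb)
    up_b <- random_dna(fb); dn_b <- random_dna(fb)
    ra <- IRanges::IRanges(); rb <- IRanges::IRanges()
    if (classes[i] != "none") {
      relic1 <- random_dna(rl)
      relic2 <- random_dna(max(2L, (2L * rl) %/% 3L))
      off1 <- sample(fb - 3L * rl, 1)              # upstream flank
      off2 <- off1 + rl + sample(100:300, 1)
      insert <- function(s, sub, at)
        paste0(substr(s, 1, at - 1), sub,
               substr(s, at + nchar(sub), nchar(s)))
      up_a <- insert(insert(up_a, relic1, off1), relic2, off2)
      up_b <- insert(insert(up_b, relic1, off1), relic2, off2)
      relic_span <- IRanges::IRanges(
        c(off1, off2), width = c(nchar(relic1), nchar(relic2)))
      if (classes[i] %in% c("both", "a_only")) ra <- relic_span
      if (classes[i] %in% c("both", "b_only")) rb <- relic_span
      relic_rows[[length(relic_rows) + 1L]] <- data.frame(
        pair = i, off1 = off1, off2 = off2, class = classes[i])
    }
    flanks_a[i] <- paste0(up_a, core, dn_a)
    flanks_b[i] <- paste0(up_b, core, dn_b)
    reps_a[[i]] <- ra; reps_b[[i]] <- rb
  }
  fam_no <- 100L + seq_len(n)
  pairs <- data.frame(
    mirna_a = sprintf("stu-miR%da", fam_no),
    mirna_b = sprintf("sly-miR%da", fam_no),
    class = classes, stringsAsFactors = FALSE)
  premirnas_a <- Biostrings::DNAStringSet(
    stats::setNames(cores, pairs$mirna_a))
  premirnas_b <- Biostrings::DNAStringSet(stats::setNames(
    vapply(cores, mutate_seq, character(1),
           divergence = 0.02, indel_frac = 0), pairs$mirna_b))
  # hairpin loci written into the genome for the mapping analysis
  genome_chars <- lapply(as.character(sim$genome),
                         function(s) strsplit(s, "")[[1]])
  loci_rows <- list()
  occupied <- lapply(names(genome_chars), function(x) IRanges::IRanges())
  names(occupied) <- names(genome_chars)
  n_ml <- min(config$n_multilocus_mirnas, n)
  for (i in seq_len(n)) {
    n_loci <- if (i <= n_ml) config$multilocus_copies else 1L
    for (k in seq_len(n_loci)) {
      for (try in 1:100) {
        ch <- sample(names(genome_chars), 1)
        start <- sample(length(genome_chars[[ch]]) - core_len, 1)
        cand <- IRanges::IRanges(start, width = core_len)
        if (!any(IRanges::overlapsAny(cand, occupied[[ch]]))) break
      }
      occupied[[ch]] <- c(occupied[[ch]], cand)
      genome_chars[[ch]][start:(start + core_len - 1L)] <-
        strsplit(cores[i], "")[[1]]
      loci_rows[[length(loci_rows) + 1L]] <- data.frame(
        mirna_id = pairs$mirna_a[i], chrom = ch, start = start,
        end = start + core_len - 1L, stringsAsFactors = FALSE)
    }
  }
  genome <- Biostrings::DNAStringSet(
    vapply(genome_chars, paste, character(1), collapse = ""))
  names(genome) <- names(sim$genome)
  list(pairs = pairs, flanks_a = flanks_a, flanks_b = flanks_b,
       repeats_a = reps_a, repeats_b = reps_b,
       relic_truth = if (length(relic_rows) > 0)
         do.call(rbind, relic_rows) else NULL,
       premirnas_a = premirnas_a, premirnas_b = premirnas_b,
       genome = genome,
       loci_truth = do.call(rbind, loci_rows))
}

#' Simulate expression counts, small-RNA reads and probe placements
#'
#' Per-member, per-condition RNA-seq counts are drawn from a negative
#' binomial with the configured family mean and dispersion.  Small-RNA
#' reads are substrings of repeat loci (either strand) with lengths
#' drawn from the configured 24-nt-peaked distribution, with the 3'
#' adapter appended.  Probes of 60 nt are tiled fully inside genes and
#' repeats (overlap fraction 1) plus a set straddling feature edges at
#' 50% overlap (expected unassigned).
#'
#' @param config A [sim_config()].
#' @param sim Output of [simulate_genome()].
#' @return A list with `counts` (matrix members x conditions),
#'   `count_features` (`GRanges` rows matching `counts`), `srna_reads`
#'   (character, adapters on), `srna_truth` (data.frame),
#'   `probe_matches` (`GRanges`), `probe_truth` (intended target per
#'   probe).
#' @export
simulate_reads <- function(config, sim) {
  set.seed(config$seed + 3L)
  reps <- sim$repeats
  mu <- config$nb_mean[reps$family_id]
  mu[is.na(mu)] <- 1
  counts <- matrix(
    stats::rnbinom(length(reps) * config$n_conditions,
                   mu = rep(mu, config$n_conditions),
                   size = config$nb_size),
    nrow = length(reps))
  rownames(counts) <- paste0("rep", seq_along(reps))
  colnames(counts) <- paste0("cond", seq_len(config$n_conditions))
  # small RNA reads from repeat loci
  lens <- as.integer(names(config$srna_len_probs))
  genome <- sim$genome
  pick <- sample(length(reps), config$srna_n_reads, replace = TRUE)
  read_len <- sample(lens, config$srna_n_reads, replace = TRUE,
                     prob = config$srna_len_probs)
  genome_chr <- as.character(genome)
  rep_chrom <- as.character(GenomicRanges::seqnames(reps))
  rep_start <- GenomicRanges::start(reps)
  rep_width <- GenomicRanges::width(reps)
  revcomp_chr <- function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  reads <- character(config$srna_n_reads)
  for (i in seq_len(config$srna_n_reads)) {
    j <- pick[i]
    L <- min(read_len[i], rep_width[j])
    off <- sample(rep_width[j] - L + 1L, 1)
    lo <- rep_start[j] + off - 1L
    s <- substr(genome_chr[[rep_chrom[j]]], lo, lo + L - 1L)
    if (stats::runif(1) < 0.5) s <- revcomp_chr(s)
    reads[i] <- paste0(s, config$srna_adapter)
  }
  srna_truth <- data.frame(repeat_idx = pick, length = read_len,
                           superfamily = reps$superfamily[pick])
  # probes
  genes <- sim$genes$genes
  probe_len <- 60L
  inside <- function(gr, n_probes, label) {
    idx <- sample(length(gr), n_probes, replace = TRUE)
    keep <- GenomicRanges::width(gr)[idx] >= probe_len
    idx <- idx[keep]
    start <- GenomicRanges::start(gr)[idx] +
      vapply(GenomicRanges::width(gr)[idx] - probe_len + 1L,
             function(m) sample(m, 1), integer(1)) - 1L
    GenomicRanges::GRanges(
      GenomicRanges::seqnames(gr)[idx],
      IRanges::IRanges(start, width = probe_len),
      target_truth = label, seqinfo = sim$assembly)
  }
  straddle <- function(gr, n_probes) {
    idx <- sample(length(gr), n_probes, replace = TRUE)
    start <- GenomicRanges::end(gr)[idx] - probe_len %/% 2L
    gr2 <- suppressWarnings(GenomicRanges::GRanges(
      GenomicRanges::seqnames(gr)[idx],
      IRanges::IRanges(start, width = probe_len),
      target_truth = "unassigned", seqinfo = sim$assembly))
    GenomicRanges::trim(gr2)
  }
  intergenic_gap <- GenomicRanges::gaps(merge_intervals(
    c(genes[, NULL], reps[, NULL])))
  intergenic_gap <- intergenic_gap[
    GenomicRanges::strand(intergenic_gap) == "*" &
      GenomicRanges::width(intergenic_gap) > probe_len + 2L]
  probes <- c(inside(genes, 40L, "gene"), inside(reps, 40L, "repeat"),
              straddle(intergenic_gap, 20L))
  probes$probe_id <- sprintf("probe%03d", seq_along(probes))
  probes$probe_len <- probe_len
  list(counts = counts, count_features = reps, srna_reads = reads,
       srna_truth = srna_truth, probe_matches = probes,
       probe_truth = probes$target_truth)
}

#' Write a simulated study to disk and validate the manifest
#'
#' Emits genome FASTA, repeat `.out`, gene GFF3 and a JSON truth
#' manifest, then reads the annotation files back and checks they
#' reproduce the manifest coordinates exactly (manifest-file
#' consistency is validated on every write).
#'
#' @param sim Output of [simulate_genome()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
  write_repeatmasker_out(sim$repeats, file.path(dir, "repeats.out"))
  write_gff3_genes(sim$genes, file.path(dir, "genes.gff3"))
  manifest <- list(
    chroms = as.list(stats::setNames(
      as.integer(GenomeInfoDb::seqlengths(sim$assembly)),
      GenomeInfoDb::seqnames(sim$assembly))),
    n_repeats = length(sim$repeats),
    n_genes = length(sim$genes),
    repeat_starts = GenomicRanges::start(sim$repeats),
    gene_ids = sim$genes$genes$gene_id)
  jsonlite::write_json(manifest, file.path(dir, "truth.json"),
                       auto_unbox = TRUE)
  back <- read_repeatmasker_out(file.path(dir, "repeats.out"),
                                sim$assembly, source = "de_novo")
  stopifnot(length(back) == length(sim$repeats),
            all(GenomicRanges::start(back) ==
                  GenomicRanges::start(sim$repeats)),
            all(GenomicRanges::end(back) ==
                  GenomicRanges::end(sim$repeats)))
  gs_back <- read_gff3_genes(file.path(dir, "genes.gff3"), sim$assembly)
  stopifnot(length(gs_back) == length(sim$genes),
            all(gs_back$genes$gene_id == sim$genes$genes$gene_id))
  invisible(dir)
}
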