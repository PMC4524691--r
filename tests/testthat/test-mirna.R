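test_that("pre-miRNA mapping finds every planted locus on both strands", {
  set.seed(81)
  hairpin <- rand_dna_str(80)
  bg <- rand_dna_str(5000)
  # plant at three loci, one as reverse complement
  genome_str <- paste0(substr(bg, 1, 1000), hairpin,
                       substr(bg, 1001, 3000), revcomp_str(hairpin),
                       substr(bg, 3001, 4000), hairpin)
  genome <- Biostrings::DNAStringSet(c(chr1 = genome_str))
  pm <- Biostrings::DNAStringSet(c(`stu-miR900a` = hairpin))
  loci <- map_premirnas(pm, genome, max_mismatch = 0)
  expect_equal(length(loci), 3L)
  expect_equal(unique(loci$mirna_id), "stu-miR900a")
  expect_equal(sort(loci$copy_index), 1:3)
  expect_equal(sum(GenomicRanges::strand(loci) == "-"), 1L)
  # absent sequence maps nowhere
  none <- map_premirnas(
    Biostrings::DNAStringSet(c(x = rand_dna_str(80))), genome)
  expect_equal(length(none), 0L)
})

test_that("mapping with mismatches equals a sliding Hamming oracle", {
  set.seed(83)
  genome_str <- rand_dna_str(3000)
  probe <- substr(genome_str, 500, 560)
  substr(probe, 10, 10) <- "A"  # may or may not introduce a mismatch
  genome <- Biostrings::DNAStringSet(c(chr1 = genome_str))
  for (mm in 0:2) {
    loci <- map_premirnas(
      Biostrings::DNAStringSet(c(`stu-miR901` = probe)), genome,
      max_mismatch = mm)
    fwd <- loci[GenomicRanges::strand(loci) == "+"]
    want <- oracle_hamming_scan(probe, genome_str, mm)
    rc_want <- oracle_hamming_scan(revcomp_str(probe), genome_str, mm)
    expect_equal(GenomicRanges::start(fwd), want, info = mm)
    expect_equal(length(loci), length(want) + length(rc_want))
  }
})

test_that("flank windows flag repeat proximity and feed the enrichment test", {
  asm <- assembly_index(c(chr1 = 100000))
  loci <- gr1(c(50000, 80000), c(50120, 80120), strand = "+",
              mirna_id = c("m1", "m2"))
  # repeat 500 bp downstream of the first hairpin only
  reps <- gr1(50620, 50800)
  fo <- mirna_flank_overlap(loci, reps, asm, flank_bp = 2000)
  expect_equal(fo$flagged, c(TRUE, FALSE))
  expect_equal(fo$n_flagged, 1L)
  expect_true(fo$p > 0 && fo$p <= 1)
  # no repeats: nothing flagged, p = 1
  fo0 <- mirna_flank_overlap(loci, GenomicRanges::GRanges(), asm)
  expect_equal(fo0$n_flagged, 0L)
  expect_equal(fo0$p, 1)
})

test_that("orthologous miRNA pairing requires family and sequence identity", {
  set.seed(85)
  core <- rand_dna_str(100)
  seqs_a <- Biostrings::DNAStringSet(c(
    `stu-miR156a` = core,
    `stu-miR398b` = rand_dna_str(100),
    `stu-miR172a` = rand_dna_str(100)))
  seqs_b <- Biostrings::DNAStringSet(c(
    `sly-miR156a` = mutate_seq(core, 0.05, indel_frac = 0),
    `sly-miR398a` = rand_dna_str(100),   # same family, unrelated sequence
    `sly-miR399a` = rand_dna_str(100)))
  pairs <- pair_orthologous_mirnas(seqs_a, seqs_b)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$mirna_a, "stu-miR156a")
  expect_equal(pairs$mirna_b, "sly-miR156a")
  expect_equal(pairs$family, "miR156")
  # name stems parse the miRBase convention
  expect_equal(mirna_family(c("stu-miR156a-5p", "sly-MIR399x", "oddball")),
               c("miR156", "MIR399", NA))
})

test_that("chained local alignment recovers planted relics and terminates", {
  set.seed(87)
  # identical flanks: one motif spanning the whole (short) region
  fl <- rand_dna_str(300)
  m0 <- chained_local_alignments(fl, fl)
  expect_gte(nrow(m0), 1L)
  expect_equal(m0$pos_a[1], m0$pos_b[1])
  expect_gte(max(m0$length), 290L)
  # planted 30-bp relic inside otherwise unrelated 2 kb flanks
  relic <- rand_dna_str(30)
  fa <- paste0(rand_dna_str(700), relic, rand_dna_str(1300))
  fb <- paste0(rand_dna_str(1100), relic, rand_dna_str(870))
  m1 <- chained_local_alignments(fa, fb)
  hit <- m1[m1$length >= 20, ]
  expect_equal(nrow(hit), 1L)
  # chance matches in the background can extend the relic by a base or
  # two; the recovered motif must cover the planted offsets
  expect_lte(hit$pos_a, 701L)
  expect_gte(hit$pos_a + hit$length - 1L, 730L)
  expect_equal(hit$pos_b - hit$pos_a, 1101L - 701L)
  # unrelated random flanks produce no high-scoring motif
  m2 <- chained_local_alignments(rand_dna_str(2000), rand_dna_str(2000))
  expect_equal(nrow(m2), 0L)
})

test_that("relics survive heavy flank divergence around them", {
  set.seed(89)
  relic <- rand_dna_str(30)
  base <- paste0(rand_dna_str(500), relic, rand_dna_str(500))
  # species B flank: everything diverged except the conserved relic
  fb <- paste0(rand_dna_str(500), relic, rand_dna_str(500))
  m <- chained_local_alignments(base, fb)
  covered <- any(m$pos_a <= 501 & m$pos_a + m$length - 1 >= 530 &
                   m$pos_a - m$pos_b == 0)
  expect_true(covered)
})

test_that("footprint calls keep repeat-supported motifs and grade strength", {
  motifs <- data.frame(
    motif_seq = c("AAAAAA", "CCCCCC"), pos_a = c(100L, 400L),
    pos_b = c(150L, 500L), length = c(6L, 8L),
    strand_consistent = TRUE)
  rep_a <- IRanges::IRanges(c(90, 380), c(120, 420))
  rep_b <- IRanges::IRanges(c(140, 480), c(170, 520))
  # both species support both motifs, collinear -> strong, class both
  call <- call_footprints(motifs, rep_a, rep_b)
  expect_equal(call$class, "both")
  expect_equal(call$strength, "strong")
  # repeat support in one species only
  call_a <- call_footprints(motifs, rep_a, IRanges::IRanges())
  expect_equal(call_a$class, "a_only")
  single <- call_footprints(motifs[1, ], IRanges::IRanges(90, 120),
                            IRanges::IRanges())
  expect_equal(single$strength, "candidate")
  # inverted order between species breaks collinearity
  inv <- motifs
  inv$pos_b <- c(500L, 150L)
  call_inv <- call_footprints(inv, rep_a, rep_b)
  expect_equal(call_inv$strength, "candidate")
  # short motifs (< 5 bp) never qualify
  short <- motifs
  short$length <- c(4L, 4L)
  expect_equal(call_footprints(short, rep_a, rep_b)$class, "none")
  # no repeat support anywhere
  expect_equal(call_footprints(motifs, IRanges::IRanges(),
                               IRanges::IRanges())$class, "none")
})

test_that("footprint classes partition simulated pairs by planted class", {
  cfg <- sim_config(seed = 91, n_genes = 6, chrom_len = 30000,
                    families = within(default_families(),
                                      n_copies <- rep(3L, 6)),
                    mirna_classes = c(both = 2L, a_only = 1L,
                                      b_only = 1L, none = 2L))
  sim <- simulate_genome(cfg)
  mir <- plant_mirna_footprints(cfg, sim)
  called <- vapply(seq_len(nrow(mir$pairs)), function(i) {
    motifs <- chained_local_alignments(mir$flanks_a[i], mir$flanks_b[i])
    call_footprints(motifs, mir$repeats_a[[i]], mir$repeats_b[[i]])$class
  }, character(1))
  expect_equal(called, mir$pairs$class)
})
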