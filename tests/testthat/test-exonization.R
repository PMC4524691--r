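test_that("global alignment matches the expected worked examples", {
  aln <- global_align("ACGT", "ACGT")
  expect_equal(aln$score, 20)
  expect_equal(aln$aligned_a, "ACGT")
  expect_equal(aln$aligned_b, "ACGT")
  aln2 <- global_align("ACGT", "AGT")
  d <- extract_diffs(aln2)
  expect_equal(nrow(d), 1L)
  expect_equal(d$kind, "insertion_a")
  expect_equal(d$length, 1L)
  expect_error(global_align("", "ACGT"), "non-empty")
})

test_that("global alignment scores equal an independent DP oracle", {
  set.seed(51)
  for (i in 1:30) {
    a <- rand_dna_str(sample(5:40, 1))
    b <- rand_dna_str(sample(5:40, 1))
    got <- global_align(a, b)$score
    want <- oracle_global_score(a, b)
    expect_equal(got, want, info = paste(a, b))
    # score symmetry
    expect_equal(global_align(b, a)$score, got)
  }
})

test_that("diff extraction merges gap runs and round-trips sequence B", {
  expect_equal(nrow(extract_diffs(global_align("ACGTACGT", "ACGTACGT"))),
               0L)
  aln <- global_align("AAACCCGGGTTTAAACCC", "AAACCCTTTAAACCC")
  d <- extract_diffs(aln)
  expect_equal(nrow(d), 1L)   # one 3-bp indel, not three 1-bp ones
  expect_equal(d$length, 3L)
  set.seed(53)
  for (i in 1:10) {
    a <- rand_dna_str(60)
    b <- mutate_seq(a, 0.1)
    aln <- global_align(a, b)
    expect_equal(gsub("-", "", aln$aligned_a), a)
    expect_equal(apply_diffs(aln), b)
  }
})

test_that("transcript intervals project through the exon ladder", {
  ex_plus <- gr1(c(101, 301), c(200, 400), strand = "+")
  seg <- transcript_to_genome(5, 20, ex_plus)
  expect_equal(GenomicRanges::start(seg), 105L)
  expect_equal(GenomicRanges::end(seg), 120L)
  # spanning the junction projects to two genomic segments
  seg2 <- transcript_to_genome(95, 110, ex_plus)
  expect_equal(length(seg2), 2L)
  expect_equal(GenomicRanges::start(seg2), c(195L, 301L))
  expect_equal(GenomicRanges::end(seg2), c(200L, 310L))
  # minus strand: transcript runs 3'->5' in genome coordinates
  ex_minus <- gr1(c(301, 101), c(400, 200), strand = "-")
  seg3 <- transcript_to_genome(1, 10, ex_minus)
  expect_equal(GenomicRanges::start(seg3), 391L)
  expect_equal(GenomicRanges::end(seg3), 400L)
  expect_error(transcript_to_genome(190, 500, ex_plus), "beyond")
})

test_that("diffs map to repeats through either species' projection", {
  exons <- gr1(c(101, 301), c(200, 400), strand = "+")
  reps <- gr1(150, 170)
  d <- data.frame(kind = c("substitution", "substitution", "insertion_a"),
                  pos_a = c(55L, 10L, 95L), pos_b = c(55L, 10L, 94L),
                  length = c(1L, 1L, 20L))
  got <- map_diffs_to_repeats(d, exons, reps, NULL,
                              GenomicRanges::GRanges())
  expect_equal(got$in_repeat_a, c(TRUE, FALSE, FALSE))
  # junction-spanning indel: overlap on either side sets the flag
  reps2 <- gr1(305, 306)
  got2 <- map_diffs_to_repeats(d, exons, reps2, NULL,
                               GenomicRanges::GRanges())
  expect_true(got2$in_repeat_a[3])
  # no repeats anywhere -> all flags false
  got3 <- map_diffs_to_repeats(d, exons, GenomicRanges::GRanges(),
                               NULL, GenomicRanges::GRanges())
  expect_false(any(got3$in_repeat_a))
})

test_that("codon propagation distinguishes synonymous and frame effects", {
  # GAA and GAG both encode Glu: substitution at codon 3, position 9
  cds_a <- "ATGAAACCCGAATTTTAA"
  cds_b <- "ATGAAACCCGAGTTTTAA"
  d <- extract_diffs(global_align(cds_a, cds_b))
  pr <- propagate_to_protein(d, cds_a, cds_b)
  expect_equal(pr$aa_changes$effect, "synonymous")
  expect_false(pr$has_aa_change)
  # in-frame 3-bp insertion -> single aa indel
  cds_c <- "ATGAAAGGGCCCGAATTTTAA"
  d2 <- extract_diffs(global_align(cds_a, cds_c))
  pr2 <- propagate_to_protein(d2, cds_a, cds_c)
  expect_true(any(pr2$aa_changes$effect == "aa_indel"))
  expect_false(any(pr2$aa_changes$effect == "frameshift"))
  # 2-bp deletion -> frameshift
  cds_d <- "ATGAAACCGAATTTTAA"
  d3 <- data.frame(kind = "insertion_a", pos_a = 8L, pos_b = 7L,
                   length = 2L)
  pr3 <- propagate_to_protein(d3, cds_a, cds_d)
  expect_true(any(pr3$aa_changes$effect == "frameshift"))
  # internal stop flags the pair for exclusion
  pr4 <- propagate_to_protein(d, "ATGTAACCCGAATTT", cds_b)
  expect_true(pr4$internal_stop)
})

test_that("amino-acid calls agree with a translate-and-diff oracle", {
  set.seed(57)
  gc <- Biostrings::GENETIC_CODE
  for (i in 1:10) {
    n_cod <- 40
    a <- paste0("ATG", paste(sample(names(gc)[gc != "*"], n_cod - 1,
                                    replace = TRUE), collapse = ""))
    b <- a
    # substitute 5 random non-start codons with stop-free codons
    touched <- sample(2:n_cod, 5)
    for (ci in touched) {
      cand <- sample(names(gc)[gc != "*"], 1)
      substr(b, (ci - 1) * 3 + 1, ci * 3) <- cand
    }
    d <- extract_diffs(global_align(a, b))
    pr <- propagate_to_protein(d, a, b)
    aa_a <- strsplit(as.character(Biostrings::translate(
      Biostrings::DNAString(a))), "")[[1]]
    aa_b <- strsplit(as.character(Biostrings::translate(
      Biostrings::DNAString(b))), "")[[1]]
    want_changed <- which(aa_a != aa_b)
    got_changed <- unique(pr$aa_changes$codon_a[
      pr$aa_changes$effect == "nonsynonymous"])
    expect_setequal(got_changed, want_changed)
  }
})

test_that("reciprocal best hits recover planted orthologs among decoys", {
  set.seed(59)
  aas <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
           "P", "Q", "R", "S", "T", "V", "W", "Y")
  rand_prot <- function(n) paste(sample(aas, n, replace = TRUE),
                                 collapse = "")
  mutate_prot <- function(p, rate) {
    ch <- strsplit(p, "")[[1]]
    hit <- which(runif(length(ch)) < rate)
    ch[hit] <- sample(aas, length(hit), replace = TRUE)
    paste(ch, collapse = "")
  }
  base <- vapply(rep(120, 6), rand_prot, character(1))
  prot_a <- Biostrings::AAStringSet(stats::setNames(
    base, paste0("a", 1:6)))
  # orthologs at ~85% identity, plus decoys on the B side
  prot_b <- Biostrings::AAStringSet(stats::setNames(
    c(vapply(base, mutate_prot, character(1), rate = 0.15),
      rand_prot(120), rand_prot(120)),
    c(paste0("b", 1:6), "decoy1", "decoy2")))
  pairs <- find_orthologs(prot_a, prot_b)
  rec <- pairs[pairs$reciprocal, ]
  expect_equal(nrow(rec), 6L)
  expect_equal(rec$gene_b[match(paste0("a", 1:6), rec$gene_a)],
               paste0("b", 1:6))
  # identical proteomes map to themselves
  self <- find_orthologs(prot_a, stats::setNames(prot_a, names(prot_a)))
  expect_true(all(self$reciprocal))
  expect_equal(self$gene_a, self$gene_b)
  expect_error(find_orthologs(prot_a[0], prot_b), "empty")
})

test_that("a duplicated paralog leaves only the better copy reciprocal", {
  set.seed(61)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  p <- paste(sample(aas, 150, replace = TRUE), collapse = "")
  near <- p
  substr(near, 1, 8) <- "AAAAAAAA"   # slightly worse copy
  prot_a <- Biostrings::AAStringSet(c(a1 = p))
  prot_b <- Biostrings::AAStringSet(c(b_good = p, b_paralog = near))
  pairs <- find_orthologs(prot_a, prot_b)
  expect_equal(pairs$gene_b[pairs$gene_a == "a1"], "b_good")
  expect_true(pairs$reciprocal[pairs$gene_a == "a1"])
})

test_that("cascade counts are monotone and respect exclusions", {
  pf <- data.frame(
    repeat_indel = c(TRUE, TRUE, FALSE, FALSE, TRUE),
    repeat_substitution = c(TRUE, FALSE, TRUE, FALSE, TRUE),
    aa_change = c(TRUE, FALSE, FALSE, TRUE, TRUE),
    structure_candidate = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    excluded = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  casc <- exonization_cascade(pf)
  expect_equal(casc$total_pairs, 5L)
  expect_equal(casc$pairs_with_repeat_indels, 2L)
  expect_equal(casc$pairs_with_repeat_substitutions, 2L)
  expect_equal(casc$pairs_with_aa_changes, 1L)
  expect_equal(casc$pairs_with_structure_candidates, 1L)
  expect_true(casc$pairs_with_aa_changes <=
                casc$pairs_with_repeat_indels +
                casc$pairs_with_repeat_substitutions)
  # monotonicity on random flag tables
  set.seed(63)
  for (i in 1:20) {
    rf <- as.data.frame(matrix(runif(40) < 0.5, ncol = 4))
    names(rf) <- c("repeat_indel", "repeat_substitution", "aa_change",
                   "structure_candidate")
    cc <- exonization_cascade(rf)
    expect_lte(cc$pairs_with_aa_changes, cc$total_pairs)
    expect_lte(cc$pairs_with_structure_candidates,
               cc$pairs_with_aa_changes)
  }
})
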