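test_that("RepeatMasker .out coordinates and strand dialect parse correctly", {
  tmp <- withr::local_tempfile(fileext = ".out")
  writeLines(c(
    " 1000 12.50  0.0  0.0 chr1 101 200 (0) + fam1 LTR/Gypsy 1 100 (0) 1",
    "  900  8.00  0.0  0.0 chr1 501 650 (0) C fam2 DNA/hAT-Ac 1 150 (0) 2"),
    tmp)
  gr <- read_repeatmasker_out(tmp)
  expect_equal(GenomicRanges::start(gr), c(101L, 501L))
  expect_equal(GenomicRanges::end(gr), c(200L, 650L))
  expect_equal(GenomicRanges::width(gr)[1], 100L)
  expect_equal(as.character(GenomicRanges::strand(gr)), c("+", "-"))
  expect_equal(gr$family_id, c("fam1", "fam2"))
  expect_equal(gr$class, c("Retrotransposon", "DNA transposon"))
  expect_equal(gr$divergence, c(0.125, 0.08))
})

test_that("malformed .out lines and out-of-assembly coordinates are rejected", {
  tmp <- withr::local_tempfile(fileext = ".out")
  writeLines(" 1000 1.0 0.0", tmp)
  expect_error(read_repeatmasker_out(tmp), "malformed")
  writeLines(
    " 1000 1.00 0.0 0.0 chr1 50 500 (0) + f LTR/Gypsy 1 100 (0) 1", tmp)
  expect_error(
    read_repeatmasker_out(tmp, assembly_index(c(chr1 = 100))),
    "outside")
  expect_error(
    read_repeatmasker_out(tmp, assembly_index(c(chr9 = 1000))),
    "absent")
})

test_that(".out write/read round trip preserves every field", {
  set.seed(11)
  n <- 50
  starts <- sample(1:5000, n)
  gr <- gr1(starts, starts + sample(50:400, n, replace = TRUE),
            strand = sample(c("+", "-"), n, replace = TRUE),
            family_id = paste0("fam", sample(9, n, replace = TRUE)),
            superfamily = sample(c("LTR/Gypsy", "DNA/TcMar-Stowaway",
                                   "LINE/L1", "RC/Helitron"), n,
                                 replace = TRUE),
            divergence = round(runif(n, 0, 0.4), 4),
            score = as.numeric(sample(100:5000, n)))
  gr$class <- repeat_class(gr$superfamily)
  gr$source <- "de_novo"
  tmp <- withr::local_tempfile(fileext = ".out")
  write_repeatmasker_out(gr, tmp)
  back <- read_repeatmasker_out(tmp, source = "de_novo")
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(gr))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(gr))
  expect_equal(as.character(GenomicRanges::strand(back)),
               as.character(GenomicRanges::strand(gr)))
  for (col in c("family_id", "superfamily", "class", "source",
                "divergence", "score"))
    expect_equal(S4Vectors::mcols(back)[[col]],
                 S4Vectors::mcols(gr)[[col]], info = col)
})

test_that("GFF3 genes assemble exons, introns and strand-aware order", {
  tmp <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1001\t2000\t.\t+\t.\tID=gA",
    "chr1\tsrc\tmRNA\t1001\t2000\t.\t+\t.\tID=gA.t1;Parent=gA",
    "chr1\tsrc\texon\t1001\t1200\t.\t+\t.\tID=gA.e1;Parent=gA.t1",
    "chr1\tsrc\texon\t1501\t2000\t.\t+\t.\tID=gA.e2;Parent=gA.t1",
    "chr1\tsrc\tgene\t5001\t6000\t.\t-\t.\tID=gB",
    "chr1\tsrc\tmRNA\t5001\t6000\t.\t-\t.\tID=gB.t1;Parent=gB",
    "chr1\tsrc\texon\t5001\t5300\t.\t-\t.\tID=gB.e1;Parent=gB.t1",
    "chr1\tsrc\texon\t5700\t6000\t.\t-\t.\tID=gB.e2;Parent=gB.t1"),
    tmp)
  gs <- read_gff3_genes(tmp)
  expect_equal(length(gs), 2L)
  intr <- introns(gs)
  expect_equal(GenomicRanges::start(intr[["gA"]]), 1201L)
  expect_equal(GenomicRanges::end(intr[["gA"]]), 1500L)
  # minus-strand exons stored 5'->3': descending genomic start
  expect_equal(GenomicRanges::start(gs$exons[["gB"]]), c(5700L, 5001L))
})

test_that("exons outside the gene span are a validation error", {
  g <- gr1(100, 200, strand = "+", gene_id = "g1")
  ex <- GenomicRanges::GRangesList(gr1(c(100, 190), c(150, 260),
                                       strand = "+"))
  expect_error(gene_set(g, ex), "outside gene span")
})

test_that("GFF3 write/read round trip preserves a multi-gene fixture", {
  cfg <- sim_config(seed = 3, n_genes = 10, chrom_len = 30000,
                    families = within(default_families(),
                                      n_copies <- rep(2L, 6)))
  sim <- simulate_genome(cfg)
  tmp <- withr::local_tempfile(fileext = ".gff3")
  write_gff3_genes(sim$genes, tmp)
  back <- read_gff3_genes(tmp, sim$assembly)
  expect_equal(length(back), 10L)
  expect_equal(back$genes$gene_id, sim$genes$genes$gene_id)
  expect_equal(lengths(back$exons), lengths(sim$genes$exons))
  expect_equal(sum(lengths(introns(back))), sum(lengths(introns(sim$genes))))
})

test_that("merge_intervals unions overlapping and abutting intervals", {
  m <- merge_intervals(gr1(c(1, 6), c(10, 20)))
  expect_equal(GenomicRanges::start(m), 1L)
  expect_equal(GenomicRanges::end(m), 20L)
  # abutting (end + 1 == start) merges too
  m2 <- merge_intervals(gr1(c(1, 11), c(10, 20)))
  expect_equal(length(m2), 1L)
  expect_equal(length(merge_intervals(GenomicRanges::GRanges())), 0L)
})

test_that("merging and coverage equal the per-base oracle on random sets", {
  set.seed(21)
  for (rep in 1:20) {
    n <- 200
    starts <- sample(1:9000, n, replace = TRUE)
    ends <- pmin(starts + sample(0:500, n, replace = TRUE), 10000L)
    gr <- gr1(starts, ends)
    m <- merge_intervals(gr)
    om <- oracle_merge(starts, ends, 10000L)
    expect_equal(GenomicRanges::start(m), om$start)
    expect_equal(GenomicRanges::end(m), om$end)
    # idempotence
    expect_identical(merge_intervals(m), m)
    # coverage within a random region
    rs <- sample(1:5000, 1); re <- rs + sample(1000:4999, 1)
    expect_equal(covered_bases(gr, gr1(rs, re)),
                 oracle_covered_bases(starts, ends, rs, re))
  }
})

test_that("covered_bases counts the union, not the sum", {
  expect_equal(covered_bases(gr1(1, 100), gr1(1, 100)), 100)
  expect_equal(covered_bases(gr1(c(1, 11), c(50, 20))), 50)
  gr <- gr1(c(1, 11), c(50, 20))
  expect_lte(covered_bases(gr), sum(GenomicRanges::width(gr)))
})

test_that("upstream windows are strand-aware and clipped at edges", {
  asm <- assembly_index(c(chr1 = 50000))
  plus <- gr1(10001, 12000, strand = "+")
  GenomeInfoDb::seqinfo(plus) <- asm
  w <- upstream_flank(plus, 5000)
  expect_equal(c(GenomicRanges::start(w), GenomicRanges::end(w)),
               c(5001L, 10000L))
  minus <- gr1(8000, 10000, strand = "-")
  GenomeInfoDb::seqinfo(minus) <- asm
  w2 <- upstream_flank(minus, 2000)
  expect_equal(c(GenomicRanges::start(w2), GenomicRanges::end(w2)),
               c(10001L, 12000L))
  near_edge <- gr1(1001, 3000, strand = "+")
  GenomeInfoDb::seqinfo(near_edge) <- asm
  w3 <- upstream_flank(near_edge, 5000)
  expect_equal(c(GenomicRanges::start(w3), GenomicRanges::end(w3)),
               c(1L, 1000L))
  expect_equal(GenomicRanges::width(w3), 1000L)
})

test_that("BED6 round trip converts coordinates at the boundary", {
  tmp <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("track name=test",
               "chr1\t100\t200\tfeat1\t5\t+",
               "chr2\t0\t50\tfeat2\t0\t-"), tmp)
  gr <- read_bed(tmp)
  # BED 0-based half-open -> 1-based closed
  expect_equal(GenomicRanges::start(gr), c(101L, 1L))
  expect_equal(GenomicRanges::end(gr), c(200L, 50L))
  expect_equal(gr$name, c("feat1", "feat2"))
  set.seed(77)
  n <- 30
  st <- sample(1000, n)
  rnd <- gr1(st, st + sample(10:500, n, replace = TRUE),
             strand = sample(c("+", "-", "*"), n, replace = TRUE),
             name = paste0("f", seq_len(n)),
             score = as.numeric(sample(0:1000, n)))
  tmp2 <- withr::local_tempfile(fileext = ".bed")
  write_bed(rnd, tmp2)
  back <- read_bed(tmp2)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(rnd))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(rnd))
  expect_equal(as.character(GenomicRanges::strand(back)),
               as.character(GenomicRanges::strand(rnd)))
  expect_equal(back$name, rnd$name)
  expect_equal(back$score, rnd$score)
})
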