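mk_genes <- function(n = 3, start0 = 10000, gap = 10000) {
  asm <- assembly_index(c(chr1 = 200000))
  g <- gr1(start0 + (0:(n - 1)) * gap, start0 + (0:(n - 1)) * gap + 999,
           strand = "+", gene_id = paste0("g", seq_len(n)))
  GenomeInfoDb::seqinfo(g) <- asm
  g
}

hit_row <- function(tf, gene, start, end, score = NA_real_)
  data.frame(tf_name = tf, gene_id = gene, chrom = "chr1",
             start = start, end = end, score = score,
             stringsAsFactors = FALSE)

test_that("promoter-window site counting honours the window edge rule", {
  genes <- mk_genes(2)
  hits <- rbind(
    hit_row("Ibox", "g1", 8100, 8105),   # inside 2 kb window (8000-9999)
    hit_row("Ibox", "g1", 9500, 9505),
    hit_row("Ibox", "g1", 9998, 10003),  # straddles edge: >=1 bp inside
    hit_row("MADS", "g2", 18100, 18105))
  counts <- count_tfbs(hits, genes)
  expect_equal(counts$count[counts$tf_name == "Ibox" &
                              counts$gene_id == "g1"], 3L)
  expect_equal(counts$count[counts$tf_name == "MADS" &
                              counts$gene_id == "g2"], 1L)
  expect_equal(counts$count[counts$tf_name == "MADS" &
                              counts$gene_id == "g1"], 0L)
  # hit outside every window warns and is skipped
  expect_warning(
    c2 <- count_tfbs(rbind(hits, hit_row("Ibox", "g2", 500, 505)),
                     genes),
    "outside")
  expect_equal(sum(c2$count), 4L)
  # empty hit table -> all-zero grid is empty (no TFs seen)
  expect_equal(nrow(count_tfbs(hits[0, ], genes)), 0L)
})

test_that("site counts equal a brute-force containment oracle", {
  set.seed(71)
  genes <- mk_genes(5)
  win_lo <- GenomicRanges::start(genes) - 2000
  n <- 120
  hits <- hit_row(sample(c("TF1", "TF2"), n, replace = TRUE),
                  sample(paste0("g", 1:5), n, replace = TRUE),
                  0, 0)
  gi <- match(hits$gene_id, genes$gene_id)
  hits$start <- win_lo[gi] + sample(-300:2300, n, replace = TRUE)
  hits$end <- hits$start + 7L
  counts <- suppressWarnings(count_tfbs(hits, genes))
  for (tf in c("TF1", "TF2")) for (g in paste0("g", 1:5)) {
    w_lo <- win_lo[match(g, genes$gene_id)]
    want <- sum(hits$tf_name == tf & hits$gene_id == g &
                  hits$end >= w_lo & hits$start <= w_lo + 1999)
    expect_equal(counts$count[counts$tf_name == tf &
                                counts$gene_id == g], want)
  }
})

test_that("gain/loss deltas enumerate the surplus sites deterministically", {
  genes <- mk_genes(1)
  hits_a <- rbind(hit_row("Ibox", "g1", 8100, 8105, score = 9),
                  hit_row("Ibox", "g1", 8500, 8505, score = 3),
                  hit_row("Ibox", "g1", 9000, 9005, score = 6),
                  hit_row("Ibox", "g1", 9500, 9505, score = 1),
                  hit_row("Ibox", "g1", 9700, 9705, score = 5))
  hits_b <- rbind(hit_row("Ibox", "gB", 8100, 8105, score = 9),
                  hit_row("Ibox", "gB", 8500, 8505, score = 3))
  genes_b <- mk_genes(1)
  genes_b$gene_id <- "gB"
  counts_a <- count_tfbs(hits_a, genes)
  counts_b <- count_tfbs(hits_b, genes_b)
  pairs <- data.frame(gene_a = "g1", gene_b = "gB")
  gl <- tfbs_gain_loss(counts_a, counts_b, pairs, hits_a, hits_b)
  expect_equal(gl$delta, 3L)
  expect_equal(gl$gaining_side, "a")
  gained <- gl$gained_sites[[1]]
  expect_equal(nrow(gained), 3L)
  # surplus = the |delta| lowest-scoring sites
  expect_setequal(gained$score, c(1, 3, 5))
  # equal counts -> no gained sites
  gl0 <- tfbs_gain_loss(counts_b, counts_b,
                        data.frame(gene_a = "gB", gene_b = "gB"),
                        hits_b, hits_b)
  expect_equal(gl0$delta, 0L)
  expect_equal(nrow(gl0$gained_sites[[1]]), 0L)
})

test_that("planted asymmetric sites are recovered as gains", {
  set.seed(73)
  genes <- mk_genes(4)
  planted_extra <- c(g1 = 3L, g2 = 0L, g3 = 2L, g4 = 5L)
  mk <- function(n_per_gene) {
    rows <- list()
    for (g in names(n_per_gene)) {
      k <- n_per_gene[[g]]
      if (k == 0) next
      lo <- GenomicRanges::start(genes)[match(g, genes$gene_id)] - 2000
      st <- lo + sample(0:1900, k)
      rows[[g]] <- hit_row(rep("TF", k), rep(g, k), st, st + 5)
    }
    do.call(rbind, rows)
  }
  base <- c(g1 = 2L, g2 = 4L, g3 = 1L, g4 = 2L)
  hits_a <- mk(base + planted_extra)
  hits_b <- mk(base)
  gl <- tfbs_gain_loss(count_tfbs(hits_a, genes),
                       count_tfbs(hits_b, genes),
                       data.frame(gene_a = genes$gene_id,
                                  gene_b = genes$gene_id),
                       hits_a, hits_b)
  expect_equal(stats::setNames(gl$delta, gl$gene_a),
               stats::setNames(as.integer(planted_extra),
                               names(planted_extra)))
})

test_that("repeat attribution fills percentages and the binomial screen", {
  genes <- mk_genes(1)
  hits_a <- rbind(hit_row("Ibox", "g1", 8100, 8105),
                  hit_row("Ibox", "g1", 8500, 8505),
                  hit_row("Ibox", "g1", 9000, 9005))
  counts_a <- count_tfbs(hits_a, genes)
  counts_b <- counts_a
  counts_b$count <- 0L
  pairs <- data.frame(gene_a = "g1", gene_b = "g1")
  gl <- tfbs_gain_loss(counts_a, counts_b, pairs, hits_a, hits_a)
  reps <- gr1(8000, 8600)   # covers two of the three gained sites
  att <- attribute_gains_to_repeats(gl, reps, reps, p0 = 0.3)
  expect_equal(att$summary$gain_total, 3L)
  expect_equal(att$summary$gain_repeat_total, 2L)
  expect_equal(att$summary$pct_repeat, 100 * 2 / 3)
  expect_equal(att$summary$binomial_p,
               enrichment_binomial(2, 3, 0.3))
  # no repeats -> zero percent everywhere
  att0 <- attribute_gains_to_repeats(gl, GenomicRanges::GRanges(),
                                     GenomicRanges::GRanges(), p0 = 0.3)
  expect_equal(att0$summary$pct_repeat, 0)
})

test_that("the gain binomial matches exact summation and handles edges", {
  expect_equal(tfbs_gain_binomial(0, 10, 0.5), 1)
  expect_true(is.na(tfbs_gain_binomial(0, 0, 0.5)))
  direct <- sum(choose(10, 8:10) * 0.5^10)
  expect_equal(tfbs_gain_binomial(8, 10, 0.5), direct, tolerance = 1e-12)
})

test_that("under uniform site placement the screen rejects at its level", {
  set.seed(77)
  # repeats cover fraction f of the window; sites placed uniformly
  f <- 0.3
  n_sites <- 40
  reps <- 500
  p <- vapply(seq_len(reps), function(i) {
    k <- rbinom(1, n_sites, f)
    tfbs_gain_binomial(k, n_sites, f)
  }, numeric(1))
  rej <- mean(p <= 0.05)
  # rejection rate at alpha = 0.05 within 3 binomial s.e. of 0.05
  # (discrete test, so the true level is conservative)
  expect_lte(rej, 0.05 + 3 * sqrt(0.05 * 0.95 / reps))
  # expected repeat share of gains tracks the coverage fraction
  expect_equal(mean(vapply(seq_len(reps), function(i)
    tfbs_pct_repeat(rbinom(1, n_sites, f), n_sites), numeric(1))),
    100 * f, tolerance = 0.05)
})
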