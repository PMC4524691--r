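#' Count TFBS hits per transcription factor per gene
#'
#' Counts binding sites inside each gene's upstream promoter window
#' (default 2 kb).  A site straddling the window edge counts when at
#' least one base lies inside; hits outside every window are skipped
#' with a warning.
#'
#' @param hits data.frame with columns `tf_name`, `gene_id`, `chrom`,
#'   `start`, `end` (1-based inclusive), optional `score`.
#' @param genes `GRanges` of gene spans with `gene_id` and seqlengths.
#' @param window_bp Promoter window width (default 2000).
#' @return data.frame with columns `tf_name`, `gene_id`, `count`
#'   covering every (TF, gene) combination seen in `hits` x `genes`.
#' @export
count_tfbs <- function(hits, genes, window_bp = 2000) {
  windows <- upstream_flank(genes, window_bp)
  names(windows) <- genes$gene_id
  tfs <- sort(unique(hits$tf_name))
  grid <- expand.grid(tf_name = tfs, gene_id = genes$gene_id,
                      stringsAsFactors = FALSE)
  grid$count <- integer(nrow(grid))
  if (nrow(hits) > 0) {
    hgr <- GenomicRanges::GRanges(hits$chrom,
                                  IRanges::IRanges(hits$start, hits$end))
    win <- windows[hits$gene_id]
    inside <- as.character(GenomicRanges::seqnames(hgr)) ==
      as.character(GenomicRanges::seqnames(win)) &
      GenomicRanges::start(hgr) <= GenomicRanges::end(win) &
      GenomicRanges::end(hgr) >= GenomicRanges::start(win)
    if (any(!inside))
      warning(sum(!inside), " hit(s) outside their gene's window; skipped")
    kept <- hits[inside, , drop = FALSE]
    if (nrow(kept) > 0) {
      tab <- table(tf_name = kept$tf_name, gene_id = kept$gene_id)
      idx <- cbind(match(grid$tf_name, rownames(tab)),
                   match(grid$gene_id, colnames(tab)))
      got <- !is.na(idx[, 1]) & !is.na(idx[, 2])
      grid$count[got] <- as.integer(tab[idx[got, , drop = FALSE]])
    }
  }
  grid
}

#' Gain/loss of TFBS between orthologous promoters
#'
#' For each TF and orthologue pair, `delta = count_a - count_b`.  The
#' species with the larger count carries `|delta|` *gained* sites; which
#' of its (possibly interleaved) sites count as the surplus is not
#' observable, so the surplus is taken deterministically as the
#' `|delta|` lowest-scoring sites (most-3' on ties or when no score is
#' available) — a conservative, reproducible choice.
#'
#' @param counts_a,counts_b Output of [count_tfbs()] for the two
#'   species.
#' @param pairs data.frame with columns `gene_a`, `gene_b`.
#' @param hits_a,hits_b The hit tables (used to enumerate gained
#'   sites).
#' @return data.frame with one row per (TF, pair): `tf_name`, `gene_a`,
#'   `gene_b`, `count_a`, `count_b`, `delta`, plus a list-column
#'   `gained_sites` of data.frames.
#' @export
tfbs_gain_loss <- function(counts_a, counts_b, pairs,
                           hits_a = NULL, hits_b = NULL) {
  ca <- stats::setNames(counts_a$count,
                        paste(counts_a$tf_name, counts_a$gene_id))
  cb <- stats::setNames(counts_b$count,
                        paste(counts_b$tf_name, counts_b$gene_id))
  tfs <- sort(union(unique(counts_a$tf_name), unique(counts_b$tf_name)))
  grid <- expand.grid(tf_name = tfs, pair = seq_len(nrow(pairs)),
                      stringsAsFactors = FALSE)
  grid$gene_a <- pairs$gene_a[grid$pair]
  grid$gene_b <- pairs$gene_b[grid$pair]
  ga <- ca[paste(grid$tf_name, grid$gene_a)]
  gb <- cb[paste(grid$tf_name, grid$gene_b)]
  grid$count_a <- ifelse(is.na(ga), 0L, ga)
  grid$count_b <- ifelse(is.na(gb), 0L, gb)
  grid$delta <- grid$count_a - grid$count_b
  surplus <- function(tf, gene, k, hits) {
    if (k == 0L || is.null(hits))
      return(data.frame(chrom = character(), start = integer(),
                        end = integer(), score = numeric()))
    h <- hits[hits$tf_name == tf & hits$gene_id == gene, , drop = FALSE]
    if (nrow(h) == 0L)
      return(data.frame(chrom = character(), start = integer(),
                        end = integer(), score = numeric()))
    if (is.null(h$score)) h$score <- NA_real_
    o <- order(ifelse(is.na(h$score), -Inf, h$score), -h$start)
    h <- h[o, , drop = FALSE][seq_len(min(k, nrow(h))), , drop = FALSE]
    data.frame(chrom = h$chrom, start = h$start, end = h$end,
               score = h$score, stringsAsFactors = FALSE)
  }
  grid$gained_sites <- lapply(seq_len(nrow(grid)), function(i) {
    d <- grid$delta[i]
    if (d > 0)
      surplus(grid$tf_name[i], grid$gene_a[i], d, hits_a)
    else if (d < 0)
      surplus(grid$tf_name[i], grid$gene_b[i], -d, hits_b)
    else
      data.frame(chrom = character(), start = integer(),
                 end = integer(), score = numeric())
  })
  grid$gaining_side <- ifelse(grid$delta > 0, "a",
                       ifelse(grid$delta < 0, "b", "none"))
  grid$pair <- NULL
  grid
}

#' Attribute gained TFBS to repeat-overlapping sequence
#'
#' A gained site counts as repeat-borne when its interval overlaps at
#' least one base of a repeat feature in the gaining species.  The
#' per-TF summary aggregates over all pairs:
#' `pct_repeat = 100 * gain_repeat_total / gain_total`, with the
#' one-sided binomial screen against the repeat-coverage null and
#' Benjamini-Hochberg q-values alongside the raw p-values.
#'
#' @param records Output of [tfbs_gain_loss()].
#' @param repeats_a,repeats_b Repeat features for the two species.
#' @param p0 Null probability that a uniformly placed site falls in a
#'   repeat; default is computed by the caller from repeat coverage of
#'   the promoter windows (see [tfbs_window_repeat_fraction()]).
#' @return A list with `records` (gained_in_repeat filled) and
#'   `summary` (per-TF data.frame: `gain_repeat_total`, `gain_total`,
#'   `pct_repeat`, `binomial_p`, `q_value`).
#' @export
attribute_gains_to_repeats <- function(records, repeats_a, repeats_b,
                                       p0 = 0.5) {
  in_repeat_n <- function(sites, repeats) {
    if (nrow(sites) == 0L) return(0L)
    gr <- GenomicRanges::GRanges(sites$chrom,
                                 IRanges::IRanges(sites$start, sites$end))
    sum(IRanges::overlapsAny(gr, repeats, ignore.strand = TRUE))
  }
  records$gained_in_repeat <- vapply(seq_len(nrow(records)), function(i) {
    side <- records$gaining_side[i]
    if (side == "none") return(0L)
    in_repeat_n(records$gained_sites[[i]],
                if (side == "a") repeats_a else repeats_b)
  }, integer(1))
  agg <- stats::aggregate(
    cbind(gain_repeat_total = records$gained_in_repeat,
          gain_total = abs(records$delta)),
    by = list(tf_name = records$tf_name), FUN = sum)
  agg$pct_repeat <- tfbs_pct_repeat(agg$gain_repeat_total, agg$gain_total)
  agg$binomial_p <- vapply(seq_len(nrow(agg)), function(i) {
    if (agg$gain_total[i] == 0L) return(NA_real_)
    tfbs_gain_binomial(agg$gain_repeat_total[i], agg$gain_total[i], p0)
  }, numeric(1))
  agg$q_value <- stats::p.adjust(agg$binomial_p, method = "BH")
  list(records = records, summary = agg)
}

#' Percentage of TFBS gain attributable to repeats
#'
#' The summary-table arithmetic: `100 * gain_repeat / gain_total`.
#'
#' @param gain_repeat Gained sites overlapping repeats.
#' @param gain_total All gained sites in the window.
#' @return Percentage (raw; present tables round to 2 decimals).
#' @export
tfbs_pct_repeat <- function(gain_repeat, gain_total) {
  ifelse(gain_total == 0, 0, 100 * gain_repeat / gain_total)
}

#' Binomial screen for repeat-borne TFBS gain
#'
#' One-sided `P(X >= gain_repeat | gain_total, p0)`; the conventional
#' significance gate is p <= 0.05.
#'
#' @param gain_repeat,gain_total Integers.
#' @param p0 Null probability (repeat fraction of the windows).
#' @return One-sided p-value (`NA` when `gain_total` is 0).
#' @export
tfbs_gain_binomial <- function(gain_repeat, gain_total, p0) {
  if (gain_total == 0) return(NA_real_)
  enrichment_binomial(gain_repeat, gain_total, p0)
}

#' Repeat-covered fraction of the promoter windows
#'
#' Data-driven default for the binomial null: the fraction of all
#' 2 kb-window bases covered by repeats.
#'
#' @param genes `GRanges` of gene spans with seqlengths.
#' @param repeats `GRanges` of repeat features.
#' @param window_bp Window width (default 2000).
#' @return Fraction in (0, 1), capped away from the boundaries.
#' @export
tfbs_window_repeat_fraction <- function(genes, repeats,
                                        window_bp = 2000) {
  win <- merge_intervals(upstream_flank(genes, window_bp))
  tot <- sum(as.numeric(GenomicRanges::width(win)))
  cov <- covered_bases(repeats, win)
  min(max(cov / tot, 1e-9), 1 - 1e-9)
}
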