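#' Repeat class from superfamily label
#'
#' Maps a RepeatMasker-style superfamily string (e.g. `LTR/Gypsy`,
#' `DNA/TcMar-Stowaway`, `RC/Helitron`) to the coarse class used by the
#' partition and abundance analyses.
#'
#' @param superfamily Character vector of superfamily labels.
#' @return Character vector over `{"DNA transposon", "Retrotransposon",
#'   "Uncategorized", "Other"}`.
#' @export
repeat_class <- function(superfamily) {
  top <- sub("/.*$", "", superfamily)
  out <- rep("Other", length(superfamily))
  out[top %in% c("DNA", "RC")] <- "DNA transposon"
  out[top %in% c("LTR", "LINE", "SINE", "Retroposon")] <- "Retrotransposon"
  out[top %in% c("Unknown", "Unspecified", "") | is.na(superfamily)] <-
    "Uncategorized"
  out
}

#' Read a RepeatMasker .out annotation file
#'
#' Parses the 15-column RepeatMasker `.out` dialect (1-based inclusive
#' coordinates, `C` marking minus-strand hits) into a `GRanges` of repeat
#' features with metadata columns `family_id`, `superfamily`, `class`,
#' `source` and `divergence` (substitution fraction in `[0,1]`).
#'
#' @param path Path to the `.out` file.
#' @param assembly Optional `Seqinfo`; if supplied, coordinates are
#'   validated against it.
#' @param source Provenance tag stored on every feature
#'   (`"de_novo"`, `"homology"`, `"domain"` or `"external"`).
#' @return `GRanges` of repeat features.
#' @export
read_repeatmasker_out <- function(path, assembly = NULL,
                                  source = "external") {
  lines <- readLines(path)
  body <- grepl("^\\s*\\d", lines)
  recs <- lines[body]
  if (length(recs) == 0L) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      family_id = character(), superfamily = character(),
      class = character(), source = character(),
      divergence = numeric(), score = numeric())
    return(gr)
  }
  fields <- strsplit(trimws(recs), "\\s+")
  n_fields <- lengths(fields)
  bad <- which(n_fields < 14L)
  if (length(bad) > 0L)
    stop("malformed RepeatMasker record at line ",
         which(body)[bad[1]], " of ", path)
  get <- function(i) vapply(fields, `[[`, character(1), i)
  begin <- suppressWarnings(as.integer(get(6)))
  end <- suppressWarnings(as.integer(get(7)))
  if (anyNA(begin) || anyNA(end))
    stop("non-numeric coordinates at line ",
         which(body)[which(is.na(begin) | is.na(end))[1]], " of ", path)
  ori <- get(9)
  strand <- ifelse(ori == "C", "-", "+")
  gr <- GenomicRanges::GRanges(
    seqnames = get(5),
    ranges = IRanges::IRanges(start = begin, end = end),
    strand = strand,
    family_id = get(10),
    superfamily = get(11),
    class = repeat_class(get(11)),
    source = source,
    divergence = as.numeric(get(2)) / 100,
    score = as.numeric(get(1)))
  if (!is.null(assembly)) gr <- validate_against_assembly(gr, assembly)
  gr
}

#' Read and write BED6 feature files
#'
#' BED uses 0-based half-open coordinates; conversion to the package's
#' 1-based closed convention happens here, at the I/O boundary.  The
#' name column round-trips through the `name` metadata column.
#'
#' @param path Path to a BED6 (or BED3+) file.
#' @param assembly Optional `Seqinfo` for validation.
#' @return `GRanges` with metadata `name` and `score`.
#' @export
read_bed <- function(path, assembly = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 3L))
    stop("malformed BED record at line ", which(lengths(f) < 3L)[1])
  col <- function(i, default) vapply(f, function(x)
    if (length(x) >= i) x[[i]] else default, character(1))
  gr <- GenomicRanges::GRanges(
    seqnames = col(1, NA_character_),
    IRanges::IRanges(as.integer(col(2, NA_character_)) + 1L,
                     as.integer(col(3, NA_character_))),
    strand = ifelse(col(6, ".") %in% c("+", "-"), col(6, "."), "*"),
    name = col(4, "."),
    score = suppressWarnings(as.numeric(col(5, "0"))))
  if (!is.null(assembly)) gr <- validate_against_assembly(gr, assembly)
  gr
}

#' @rdname read_bed
#' @param features `GRanges` to write.
#' @export
write_bed <- function(features, path) {
  name <- if (!is.null(features$name)) features$name else
    rep(".", length(features))
  score <- if (!is.null(features$score)) features$score else
    rep(0, length(features))
  strand <- as.character(GenomicRanges::strand(features))
  strand[strand == "*"] <- "."
  writeLines(sprintf("%s\t%d\t%d\t%s\t%g\t%s",
                     as.character(GenomicRanges::seqnames(features)),
                     GenomicRanges::start(features) - 1L,
                     GenomicRanges::end(features),
                     name, score, strand), path)
  invisible(path)
}

#' Write repeat features in RepeatMasker .out layout
#'
#' Inverse of [read_repeatmasker_out()]: emits the 15-column dialect with
#' 1-based inclusive coordinates and `C` for minus-strand features, so a
#' write/read round trip preserves every field.
#'
#' @param repeats `GRanges` from [read_repeatmasker_out()] or the
#'   simulator.
#' @param path Output path.
#' @export
write_repeatmasker_out <- function(repeats, path) {
  header <- c(
    paste("  SW   perc perc perc  query     position in query    ",
          "matching repeat         position in repeat"),
    paste("score   div. del. ins.  sequence  begin end    (left)  ",
          "repeat    class/family      begin end  (left) ID"),
    "")
  score <- if (!is.null(repeats$score)) repeats$score else
    rep(0, length(repeats))
  div <- if (!is.null(repeats$divergence)) repeats$divergence * 100 else
    rep(0, length(repeats))
  rows <- sprintf(
    "%6.0f %6.2f %4.1f %4.1f %-12s %8d %8d (%d) %s %-18s %-18s %6d %6d (%d) %d",
    score, div, 0, 0,
    as.character(GenomicRanges::seqnames(repeats)),
    GenomicRanges::start(repeats), GenomicRanges::end(repeats), 0L,
    ifelse(as.character(GenomicRanges::strand(repeats)) == "-", "C", "+"),
    repeats$family_id, repeats$superfamily,
    1L, GenomicRanges::width(repeats), 0L, seq_along(repeats))
  writeLines(c(header, rows), path)
  invisible(path)
}
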