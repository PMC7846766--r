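#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps
#'   countOverlaps reduce pintersect mcols mcols<- granges sort
#' @importFrom IRanges IRanges overlapsAny subjectHits queryHits
#' @importFrom S4Vectors queryHits subjectHits mcols DataFrame
#' @importFrom stats quantile rbinom rgamma rlnorm rmultinom rpois runif
#'   sd t.test wilcox.test median setNames ks.test
#' @importFrom utils read.table write.table head
NULL

# ---------------------------------------------------------------------------
# Genome tables
# ---------------------------------------------------------------------------

#' Construct a genome table
#'
#' A genome table records chromosome names and lengths (bp). It bounds all
#' interval validation and same-chromosome shuffling.
#'
#' @param chrom character vector of chromosome names (unique).
#' @param length integer vector of chromosome lengths in bp (> 0).
#' @return A `data.frame` with columns `chrom` and `length`.
#' @export
genome_table <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (anyDuplicated(chrom)) stop("duplicated chromosome names in genome table")
  if (length(chrom) != base::length(length))
    stop("chrom and length differ in length")
  if (any(!is.finite(length)) || any(length <= 0))
    stop("chromosome lengths must be finite and > 0")
  data.frame(chrom = chrom, length = length, stringsAsFactors = FALSE)
}

#' Read a chrom.sizes file (name<TAB>length)
#' @param path path to a two-column tab-delimited file.
#' @return genome table (see [genome_table()]).
#' @export
read_chrom_sizes <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   colClasses = c("character", "numeric"))
  genome_table(df[[1]], df[[2]])
}

.seqlengths_of <- function(genome) {
  stats::setNames(genome$length, genome$chrom)
}

# validate a GRanges against a genome table; warn on unmatched chromosomes
.check_genome <- function(gr, genome, what = "interval") {
  if (is.null(genome)) return(invisible(gr))
  sl <- .seqlengths_of(genome)
  chr <- as.character(GenomicRanges::seqnames(gr))
  unknown <- setdiff(unique(chr), names(sl))
  if (length(unknown))
    warning("chromosomes absent from genome table: ",
            paste(unknown, collapse = ", "))
  known <- chr %in% names(sl)
  bad <- known & (GenomicRanges::end(gr) > sl[chr] |
                    GenomicRanges::start(gr) < 1)
  if (any(bad))
    stop(sum(bad), " ", what, "(s) out of chromosome bounds (first: ",
         chr[bad][1], ":", GenomicRanges::start(gr)[bad][1] - 1, "-",
         GenomicRanges::end(gr)[bad][1], ")")
  invisible(gr)
}

# ---------------------------------------------------------------------------
# Interval I/O: BED / broadPeak <-> GRanges (BED is 0-based half-open; GRanges
# are 1-based closed; conversion happens here and only here)
# ---------------------------------------------------------------------------

.bed_to_granges <- function(chrom, start0, end0, name = NULL, score = NULL,
                            genome = NULL) {
  bad <- !is.finite(start0) | !is.finite(end0) | start0 < 0 | start0 >= end0
  if (any(bad))
    stop("invalid interval(s): start must satisfy 0 <= start < end (first bad record: ",
         chrom[bad][1], ":", start0[bad][1], "-", end0[bad][1], ")")
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start = start0 + 1, end = end0))
  if (!is.null(name)) S4Vectors::mcols(gr)$name <- as.character(name)
  if (!is.null(score)) S4Vectors::mcols(gr)$score <- as.numeric(score)
  .check_genome(gr, genome)
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

# locate the first malformed line for a parse-error message
.first_bad_line <- function(path, min_fields) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    if (!nzchar(lines[i])) next
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < min_fields) return(i)
    if (is.na(suppressWarnings(as.numeric(f[2]))) ||
        is.na(suppressWarnings(as.numeric(f[3])))) return(i)
  }
  NA_integer_
}

#' Read intervals from a BED3+ or ENCODE broadPeak file
#'
#' broadPeak columns 4 (name) and 7 (signalValue) are preserved as `name` and
#' `score` metadata; a plain BED score column 5 is used when column 7 is
#' absent.
#'
#' @param path tab-delimited file with at least chrom, start, end.
#' @param genome optional genome table; out-of-bounds records are an error.
#' @return A sorted `GRanges`.
#' @export
read_intervals <- function(path, genome = NULL) {
  df <- tryCatch(
    read.table(path, sep = "\t", header = FALSE, comment.char = "#",
               quote = "", stringsAsFactors = FALSE),
    error = function(e) {
      bad <- .first_bad_line(path, 3)
      stop("malformed BED/broadPeak file '", path, "'",
           if (!is.na(bad)) paste0(" at line ", bad), ": ",
           conditionMessage(e), call. = FALSE)
    })
  if (ncol(df) < 3) {
    bad <- .first_bad_line(path, 3)
    stop("malformed BED/broadPeak file '", path, "'",
         if (!is.na(bad)) paste0(" at line ", bad),
         ": fewer than 3 columns", call. = FALSE)
  }
  if (!is.numeric(df[[2]]) || !is.numeric(df[[3]])) {
    bad <- .first_bad_line(path, 3)
    stop("malformed BED/broadPeak file '", path, "'",
         if (!is.na(bad)) paste0(" at line ", bad),
         ": non-numeric coordinates", call. = FALSE)
  }
  name <- if (ncol(df) >= 4) df[[4]] else NULL
  score <- if (ncol(df) >= 7) df[[7]] else if (ncol(df) >= 5) df[[5]] else NULL
  .bed_to_granges(df[[1]], df[[2]], df[[3]], name = name, score = score,
                  genome = genome)
}

#' Write intervals to a BED file (0-based half-open), with optional
#' name/score metadata columns.
#' @param gr a `GRanges`.
#' @param path output path.
#' @export
write_intervals <- function(gr, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1,
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  mc <- S4Vectors::mcols(gr)
  if (!is.null(mc$name)) df$name <- mc$name
  if (!is.null(mc$score)) {
    if (is.null(df$name)) df$name <- "."
    df$score <- mc$score
  }
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Signal tracks (bedGraph)
# ---------------------------------------------------------------------------

#' Read a 4-column bedGraph into a signal track
#'
#' A signal track is a sorted `GRanges` of non-overlapping runs with a
#' numeric `score` (signal value, e.g. RPM coverage). Absent coverage reads
#' as 0. Overlapping input runs are rejected as ambiguous coverage.
#'
#' @param path 4-column bedGraph file.
#' @param genome optional genome table for bounds checking.
#' @return A `GRanges` with a `score` column.
#' @export
read_signal <- function(path, genome = NULL) {
  if (file.size(path) == 0) return(signal_track(character(), numeric(),
                                               numeric(), numeric()))
  df <- tryCatch(
    read.table(path, sep = "\t", header = FALSE, comment.char = "#",
               quote = "", stringsAsFactors = FALSE,
               colClasses = c("character", "numeric", "numeric", "numeric")),
    error = function(e) {
      bad <- .first_bad_line(path, 4)
      stop("malformed bedGraph file '", path, "'",
           if (!is.na(bad)) paste0(" at line ", bad), ": ",
           conditionMessage(e), call. = FALSE)
    })
  signal_track(df[[1]], df[[2]], df[[3]], df[[4]], genome = genome)
}

#' Build a signal track from run vectors (BED-style 0-based coordinates)
#' @param chrom,start0,end0,value parallel run vectors.
#' @param genome optional genome table.
#' @return sorted non-overlapping `GRanges` with `score`.
#' @export
signal_track <- function(chrom, start0, end0, value, genome = NULL) {
  if (length(chrom) == 0) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr)$score <- numeric(0)
    return(gr)
  }
  if (any(!is.finite(value)) || any(value < 0))
    stop("signal values must be finite and >= 0")
  o <- order(chrom, start0, end0)
  chrom <- as.character(chrom)[o]
  start0 <- as.numeric(start0)[o]
  end0 <- as.numeric(end0)[o]
  value <- as.numeric(value)[o]
  bad <- !is.finite(start0) | !is.finite(end0) | start0 < 0 | start0 >= end0
  if (any(bad))
    stop("invalid run(s): start must satisfy 0 <= start < end (first bad record: ",
         chrom[bad][1], ":", start0[bad][1], "-", end0[bad][1], ")")
  # overlap within chromosome is ambiguous coverage; runs are sorted, so an
  # overlap shows up between consecutive runs of the same chromosome
  n <- length(chrom)
  if (n > 1) {
    same <- chrom[-1] == chrom[-n]
    if (any(same & start0[-1] < end0[-n]))
      stop("overlapping runs in signal track: coverage is ambiguous")
  }
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end0))
  S4Vectors::mcols(gr)$score <- value
  .check_genome(gr, genome, "run")
  gr
}

#' Write a signal track as bedGraph
#' @param track signal track `GRanges`.
#' @param path output path.
#' @export
write_signal <- function(track, path) {
  df <- data.frame(as.character(GenomicRanges::seqnames(track)),
                   GenomicRanges::start(track) - 1,
                   GenomicRanges::end(track),
                   S4Vectors::mcols(track)$score)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Total signal mass over regions (value x bp)
#'
#' For each region, sums run value times overlapped width over every track
#' run intersecting the region; bases with no coverage contribute 0.
#'
#' @param track signal track `GRanges` (from [read_signal()] or
#'   [signal_track()]).
#' @param regions `GRanges` of query regions.
#' @return numeric vector, one value-bp total per region.
#' @export
region_signal <- function(track, regions) {
  out <- numeric(length(regions))
  if (length(track) == 0 || length(regions) == 0) return(out)
  hits <- GenomicRanges::findOverlaps(regions, track)
  if (length(hits) == 0) return(out)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  ow <- pmin(GenomicRanges::end(regions)[q], GenomicRanges::end(track)[s]) -
    pmax(GenomicRanges::start(regions)[q], GenomicRanges::start(track)[s]) + 1
  contrib <- ow * S4Vectors::mcols(track)$score[s]
  tapply_sum <- tapply(contrib, q, sum)
  out[as.integer(names(tapply_sum))] <- as.numeric(tapply_sum)
  out
}

#' Which query intervals overlap any subject interval (>= 1 bp)
#' @param query,subject `GRanges`.
#' @return logical vector along `query`.
#' @export
overlaps_any <- function(query, subject) {
  if (length(subject) == 0) return(rep(FALSE, length(query)))
  IRanges::overlapsAny(query, subject, ignore.strand = TRUE)
}

# ---------------------------------------------------------------------------
# Two-anchor interaction (BEDPE-like) I/O
# ---------------------------------------------------------------------------

#' Read a two-anchor loop list (BEDPE-like)
#'
#' Expects chrom1 start1 end1 chrom2 start2 end2 [score]; coordinates BED
#' 0-based half-open. Exact-coordinate duplicate records are removed (the
#' number dropped is reported via a message).
#'
#' @param path tab-delimited loop file.
#' @param genome optional genome table.
#' @param dedup drop exact duplicate records (default TRUE).
#' @return A `data.frame` of class `interaction_set` with columns
#'   chrom1,start1,end1,chrom2,start2,end2 (0-based half-open) and optional
#'   score.
#' @export
read_interactions <- function(path, genome = NULL, dedup = TRUE) {
  df <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                   quote = "", stringsAsFactors = FALSE)
  if (ncol(df) < 6) stop("loop file needs at least 6 columns")
  x <- interaction_set(df[[1]], df[[2]], df[[3]], df[[4]], df[[5]], df[[6]],
                       score = if (ncol(df) >= 7) df[[7]] else NULL,
                       genome = genome, dedup = dedup)
  x
}

#' Construct an interaction set from anchor coordinates (0-based half-open)
#' @param chrom1,start1,end1,chrom2,start2,end2 anchor coordinate vectors.
#' @param score optional numeric (e.g. read count).
#' @param genome optional genome table.
#' @param dedup drop exact-coordinate duplicates.
#' @return `interaction_set` data.frame.
#' @export
interaction_set <- function(chrom1, start1, end1, chrom2, start2, end2,
                            score = NULL, genome = NULL, dedup = TRUE) {
  df <- data.frame(chrom1 = as.character(chrom1), start1 = as.numeric(start1),
                   end1 = as.numeric(end1),
                   chrom2 = as.character(chrom2), start2 = as.numeric(start2),
                   end2 = as.numeric(end2), stringsAsFactors = FALSE)
  if (!is.null(score)) df$score <- as.numeric(score)
  if (any(df$start1 >= df$end1 | df$start2 >= df$end2 |
          df$start1 < 0 | df$start2 < 0))
    stop("invalid anchor interval(s) in interaction set")
  if (dedup) {
    key <- paste(df$chrom1, df$start1, df$end1, df$chrom2, df$start2, df$end2)
    dup <- duplicated(key)
    if (any(dup)) {
      message(sum(dup), " exact-duplicate interaction record(s) removed")
      df <- df[!dup, , drop = FALSE]
    }
  }
  rownames(df) <- NULL
  .check_genome(anchor_granges(df, 1), genome, "anchor")
  .check_genome(anchor_granges(df, 2), genome, "anchor")
  class(df) <- c("interaction_set", "data.frame")
  df
}

#' Extract one anchor side of an interaction set as GRanges
#' @param x an `interaction_set`.
#' @param which 1 or 2.
#' @return `GRanges` parallel to the rows of `x`.
#' @export
anchor_granges <- function(x, which = 1) {
  stopifnot(which %in% c(1, 2))
  if (nrow(x) == 0) return(GenomicRanges::GRanges())
  if (which == 1)
    GenomicRanges::GRanges(x$chrom1, IRanges::IRanges(x$start1 + 1, x$end1))
  else
    GenomicRanges::GRanges(x$chrom2, IRanges::IRanges(x$start2 + 1, x$end2))
}

#' Write an interaction set as BEDPE-like TSV
#' @param x `interaction_set`.
#' @param path output path.
#' @export
write_interactions <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
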