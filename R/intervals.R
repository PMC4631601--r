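# Genomic intervals are held as BED-native 0-based half-open [start, end)
# triples. SNP positions coming from VCF (1-based) are converted once, on
# load; a SNP at internal position p overlaps [s, e) iff s <= p < e.
# Interval arithmetic (sorting, merging, intersection, overlap lookup) is
# delegated to IRanges/GenomicRanges; the half-open <-> 1-based-closed
# conversion lives only in the two helpers below.

#' Construct a peak set
#'
#' A `peak_set` is a labelled collection of genomic intervals in 0-based
#' half-open coordinates, kept sorted by (chrom, start) and merged so that no
#' two intervals on the same chromosome overlap or touch ambiguously.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; each interval is `[start, end)` with
#'   `start < end`.
#' @param label single string naming the set (a cell line or tissue).
#' @return An object of class `peak_set` with elements `label` and
#'   `intervals` (a data.frame with columns chrom, start, end).
#' @export
peak_set <- function(chrom = character(), start = integer(), end = integer(),
                     label = "peaks") {
  if (length(chrom) != length(start) || length(start) != length(end))
    stop_mg("chrom, start and end must have equal length")
  if (length(start)) {
    if (any(!is.finite(start)) || any(!is.finite(end)))
      stop_mg("interval coordinates must be finite")
    if (any(start != floor(start)) || any(end != floor(end)))
      stop_mg("interval coordinates must be integers")
    if (any(start < 0)) stop_mg("interval starts must be >= 0")
    if (any(start >= end)) stop_mg("intervals must satisfy start < end")
    if (any(!nzchar(chrom))) stop_mg("chromosome names must be non-empty")
  }
  gr <- GenomicRanges::reduce(intervals_to_gr(chrom, start, end))
  out <- list(label = as.character(label), intervals = gr_to_intervals(gr))
  class(out) <- "peak_set"
  out
}

# 0-based half-open -> GRanges (1-based closed)
intervals_to_gr <- function(chrom, start, end) {
  GenomicRanges::GRanges(
    seqnames = as.character(chrom),
    ranges = IRanges::IRanges(start = as.integer(start) + 1L,
                              end = as.integer(end))
  )
}

gr_to_intervals <- function(gr) {
  gr <- GenomicRanges::sort(gr)
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

peakset_to_gr <- function(ps) {
  intervals_to_gr(ps$intervals$chrom, ps$intervals$start, ps$intervals$end)
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set '%s': %d intervals, %d bp on %d chromosome(s)>\n",
              x$label, nrow(x$intervals), peak_width(x),
              length(unique(x$intervals$chrom))))
  invisible(x)
}

#' Total number of base pairs covered by a peak set
#' @param ps a `peak_set`.
#' @return integer total width.
#' @export
peak_width <- function(ps) {
  stopifnot(inherits(ps, "peak_set"))
  if (!nrow(ps$intervals)) return(0L)
  as.integer(sum(ps$intervals$end - ps$intervals$start))
}

#' Intersect two peak sets base-by-base
#'
#' Returns exactly the base pairs present in both inputs. The operation is
#' associative and commutative, so tissue-level peak sets can be built by
#' folding it over the member cell lines.
#'
#' @param a,b `peak_set` objects.
#' @param label label for the result (default combines the inputs).
#' @return A `peak_set`.
#' @export
intersect_peaks <- function(a, b, label = NULL) {
  stopifnot(inherits(a, "peak_set"), inherits(b, "peak_set"))
  gr <- GenomicRanges::intersect(peakset_to_gr(a), peakset_to_gr(b))
  iv <- gr_to_intervals(gr)
  out <- list(
    label = if (is.null(label)) paste(a$label, b$label, sep = " & ") else label,
    intervals = iv
  )
  class(out) <- "peak_set"
  out
}

#' Read a BED3 file into a peak set
#'
#' Accepts whitespace- or tab-delimited files with at least three columns
#' (chrom, start, end); extra columns are ignored. Coordinates must be
#' non-negative integers with start < end; malformed lines are rejected with
#' the file name and line number rather than coerced. Gzip-compressed files
#' are read transparently.
#'
#' @param path path to a BED file (optionally .gz).
#' @param label label for the resulting set; defaults to the file name.
#' @return A `peak_set` (sorted, merged).
#' @export
read_bed <- function(path, label = NULL) {
  if (!file.exists(path)) stop_mg("BED file not found: %s", path)
  lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  keep <- which(nzchar(trimws(lines)) &
                  !grepl("^(#|track|browser)", trimws(lines)))
  chrom <- character(length(keep)); start <- end <- numeric(length(keep))
  for (k in seq_along(keep)) {
    i <- keep[k]
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) < 3)
      stop_mg("%s line %d: expected >= 3 columns, found %d", path, i, length(f))
    s <- suppressWarnings(as.numeric(f[2])); e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e) || s != floor(s) || e != floor(e))
      stop_mg("%s line %d: non-integer coordinates '%s' '%s'", path, i, f[2], f[3])
    if (s < 0) stop_mg("%s line %d: negative start %s", path, i, f[2])
    if (s >= e) stop_mg("%s line %d: start >= end (%s >= %s)", path, i, f[2], f[3])
    chrom[k] <- f[1]; start[k] <- s; end[k] <- e
  }
  ps <- peak_set(chrom, start, end,
                 label = if (is.null(label)) basename(path) else label)
  ps
}

#' Write a peak set as BED3
#' @param ps a `peak_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(ps, path) {
  stopifnot(inherits(ps, "peak_set"))
  write.table(ps$intervals, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
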