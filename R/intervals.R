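#' Genome model
#'
#' A genome is an ordered set of chromosomes with their lengths in base
#' pairs. All interval coordinates in this package are 0-based, half-open
#' (BED dialect): an interval covers bases `start .. end - 1`.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp),
#'   names are chromosome identifiers.
#' @return An object of class `"genome"`: a named numeric vector.
#' @examples
#' g <- genome(c(chr1 = 1e6, chr2 = 5e5))
#' @export
genome <- function(chrom_lengths) {
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    stop("chromosome lengths must be named")
  if (anyDuplicated(names(chrom_lengths)))
    stop("chromosome names must be unique")
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0))
    stop("chromosome lengths must be positive")
  structure(as.numeric(chrom_lengths), names = names(chrom_lengths),
            class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat("genome with", length(x), "chromosome(s),",
      format(sum(x), big.mark = ","), "bp\n")
  print(structure(as.numeric(x), names = names(x)))
  invisible(x)
}

#' Construct a table of genomic intervals
#'
#' Intervals are plain data frames with columns `chrom`, `start`, `end`
#' (0-based half-open) and `strand` (`"+"`, `"-"` or `"."`). Extra columns
#' are carried along by all interval operations.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Numeric vectors, `0 <= start < end`.
#' @param strand Strand, recycled; defaults to `"."`.
#' @param ... Additional columns.
#' @param genome Optional [genome()] against which coordinates are validated.
#' @return A `data.frame` of intervals.
#' @export
gintervals <- function(chrom, start, end, strand = ".", ..., genome = NULL) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end),
                   strand = rep_len(as.character(strand), length(chrom)),
                   ..., stringsAsFactors = FALSE)
  validate_intervals(df, genome)
  df
}

#' Validate an interval table
#'
#' @param x Interval data frame.
#' @param genome Optional [genome()]; if given, chromosome names must be
#'   present in it and `end` must not exceed the chromosome length.
#' @return `x`, invisibly.
#' @export
validate_intervals <- function(x, genome = NULL) {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) == 0) return(invisible(x))
  if (any(x$start < 0) || any(x$start >= x$end))
    stop("intervals must satisfy 0 <= start < end")
  if (!is.null(genome)) {
    bad <- setdiff(unique(x$chrom), names(genome))
    if (length(bad))
      stop("unknown chromosome(s): ", paste(bad, collapse = ", "))
    if (any(x$end > genome[x$chrom]))
      stop("interval end exceeds chromosome length")
  }
  invisible(x)
}

# interval df -> GRanges (1-based closed internally), and back
as_granges <- function(x) {
  strand <- if ("strand" %in% names(x)) {
    s <- x$strand
    s[!s %in% c("+", "-")] <- "*"
    s
  } else "*"
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(start = x$start + 1, end = x$end),
                         strand = strand)
}

from_granges <- function(gr) {
  s <- as.character(GenomicRanges::strand(gr))
  s[s == "*"] <- "."
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             strand = s, stringsAsFactors = FALSE)
}

#' Test whether intervals overlap
#'
#' Half-open overlap: intervals sharing only an endpoint do not overlap.
#' `a` and `b` are recycled against each other element-wise.
#'
#' @param a,b Interval data frames (see [gintervals()]).
#' @param genome Optional [genome()]; unknown chromosomes raise an error.
#' @return Logical vector.
#' @examples
#' a <- gintervals("chr1", 100, 200)
#' b <- gintervals("chr1", 150, 300)
#' interval_overlaps(a, b)  # TRUE
#' @export
interval_overlaps <- function(a, b, genome = NULL) {
  validate_intervals(a, genome); validate_intervals(b, genome)
  n <- max(nrow(a), nrow(b))
  ia <- rep_len(seq_len(nrow(a)), n); ib <- rep_len(seq_len(nrow(b)), n)
  a$chrom[ia] == b$chrom[ib] &
    a$start[ia] < b$end[ib] & b$start[ib] < a$end[ia]
}

#' Merge intervals into a sorted non-overlapping union
#'
#' Strand is discarded; abutting intervals (shared endpoint under half-open
#' coordinates) are merged.
#'
#' @param x Interval data frame.
#' @return Sorted, disjoint interval data frame covering the same bases.
#' @export
merge_intervals <- function(x) {
  validate_intervals(x)
  if (nrow(x) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), strand = character(),
                      stringsAsFactors = FALSE))
  x$strand <- "."
  out <- from_granges(GenomicRanges::reduce(as_granges(x), ignore.strand = TRUE))
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Randomly re-place intervals across a genome
#'
#' Draws, for each input interval, a chromosome with probability
#' proportional to chromosome length (among chromosomes long enough to hold
#' it) and a start uniform on the valid range, preserving each interval's
#' length. Placed intervals may overlap each other. This is the permutation
#' move behind occupancy enrichment testing.
#'
#' @param x Interval data frame.
#' @param genome A [genome()].
#' @param seed Integer seed for reproducibility (`NULL` = current stream).
#' @return Interval data frame with the same widths as `x`.
#' @export
random_placement <- function(x, genome, seed = NULL) {
  validate_intervals(x)
  stopifnot(inherits(genome, "genome"))
  widths <- x$end - x$start
  if (any(widths > max(genome)))
    stop("interval longer than every chromosome")
  with_seed(seed, {
    n <- nrow(x)
    chrom_idx <- integer(n)
    fits_all <- widths <= min(genome)
    if (any(fits_all))
      chrom_idx[fits_all] <- sample.int(length(genome), sum(fits_all),
                                        replace = TRUE, prob = genome)
    for (i in which(!fits_all)) {
      ok <- which(genome >= widths[i])
      chrom_idx[i] <- if (length(ok) == 1) ok else
        sample(ok, 1, prob = genome[ok])
    }
    L <- genome[chrom_idx]
    start <- floor(stats::runif(n, 0, L - widths + 1))
    start <- pmin(start, L - widths)  # guard the runif upper edge
    data.frame(chrom = names(genome)[chrom_idx], start = start,
               end = start + widths, strand = ".", stringsAsFactors = FALSE)
  })
}
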