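#' Read a chromosome-sizes file into a genome
#'
#' Two tab-separated columns: chromosome name, length.
#'
#' @param path File path.
#' @return A [genome()].
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          stringsAsFactors = FALSE)
  genome(structure(df$length, names = df$chrom))
}

#' @rdname read_chrom_sizes
#' @param genome A [genome()] to write.
#' @export
write_chrom_sizes <- function(genome, path) {
  utils::write.table(data.frame(names(genome), as.numeric(genome)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read and write BED interval files
#'
#' BED3/BED6 plus optional extra numeric columns (e.g. a footprint
#' occupancy posterior in column 7). Tab-separated, no header, 0-based
#' half-open coordinates.
#'
#' @param path File path.
#' @param extra_cols Optional character vector naming columns after the
#'   first six (reading stops at the columns actually present).
#' @return Interval data frame.
#' @export
read_bed <- function(path, extra_cols = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  base <- c("chrom", "start", "end", "name", "score", "strand")
  nm <- c(base, extra_cols)[seq_len(ncol(df))]
  names(df) <- nm
  if (!"strand" %in% names(df)) df$strand <- "."
  validate_intervals(df)
  df
}

#' @rdname read_bed
#' @param x Interval data frame; columns beyond chrom/start/end/name/score/
#'   strand are appended in order.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(x))
  # BED columns are positional: stop at the first missing one
  keep <- cols[seq_len(match(FALSE, c("chrom", "start", "end", "name",
                                      "score", "strand") %in% names(x),
                             nomatch = 7L) - 1L)]
  extra <- setdiff(names(x), c("chrom", "start", "end", "name", "score",
                               "strand"))
  utils::write.table(x[c(keep, extra)], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write BEDPE loop files
#'
#' Six positional columns (chrom1, start1, end1, chrom2, start2, end2)
#' followed by any extra columns (e.g. per-condition loop strengths).
#'
#' @param path File path.
#' @param extra_cols Names for columns after the sixth.
#' @return Data frame with the two anchors.
#' @export
read_bedpe <- function(path, extra_cols = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  nm <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
          extra_cols)
  names(df)[seq_len(min(ncol(df), length(nm)))] <- nm[seq_len(min(ncol(df), length(nm)))]
  df
}

#' @rdname read_bedpe
#' @param x Loop data frame.
#' @export
write_bedpe <- function(x, path) {
  stopifnot(all(c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
                %in% names(x)))
  first <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  utils::write.table(x[c(first, setdiff(names(x), first))], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read and write gene sets in GMT format
#'
#' @param path File path.
#' @return Named list of character vectors (gene sets).
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @param description Second GMT column, recycled.
#' @export
write_gmt <- function(sets, path, description = "na") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description, sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write sparse count matrices (MatrixMarket + TSVs)
#'
#' The on-disk layout is the common triplet: `matrix.mtx` with genes as
#' rows and cells as columns, `genes.tsv` and `cells.tsv` (one identifier
#' per line; `cells.tsv` may carry extra tab-separated metadata columns
#' with a header).
#'
#' @param dir Directory holding `matrix.mtx`, `genes.tsv`, `cells.tsv`.
#' @return List with `counts` (cells x genes dense matrix) and `cell_meta`.
#' @export
read_mtx_counts <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  genes <- readLines(file.path(dir, "genes.tsv"))
  cells <- utils::read.table(file.path(dir, "cells.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
  counts <- t(as.matrix(m))
  dimnames(counts) <- list(cells[[1]], genes)
  list(counts = counts, cell_meta = cells)
}

#' @rdname read_mtx_counts
#' @param counts Cells x genes matrix.
#' @param cell_meta Data frame of per-cell metadata, first column = cell id.
#' @export
write_mtx_counts <- function(counts, cell_meta, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(methods::as(t(counts), "CsparseMatrix"),
                              "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(colnames(counts), file.path(dir, "genes.tsv"))
  utils::write.table(cell_meta, file.path(dir, "cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read and write numeric TSV matrices
#'
#' Rows are features (genes, cisREs), columns are samples/cell types; a
#' header row and row-name first column are expected.
#'
#' @param path File path.
#' @return Numeric matrix with dimnames.
#' @export
read_tsv_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  as.matrix(df)
}

#' @rdname read_tsv_matrix
#' @param x Numeric matrix.
#' @export
write_tsv_matrix <- function(x, path) {
  utils::write.table(data.frame(id = rownames(x), x, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSS table
#'
#' Four tab-separated columns with header: gene, chrom, pos (0-based bp of
#' the transcription start site), strand.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_tss_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Read a JASPAR-style position frequency matrix file
#'
#' Format: a `>name` header line followed by four lines
#' `A [ 1 2 3 ... ]` (rows A, C, G, T). Several motifs per file are
#' allowed.
#'
#' @param path File path.
#' @return Named list of 4 x w numeric matrices with rownames A,C,G,T.
#' @export
read_pfm <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no motif headers ('>') found in ", path)
  out <- list()
  for (i in seq_along(starts)) {
    hdr <- sub("^>\\s*", "", lines[starts[i]])
    block <- lines[(starts[i] + 1):(starts[i] + 4)]
    rows <- lapply(block, function(l) {
      l <- gsub("[][]", " ", l)
      v <- strsplit(trimws(l), "\\s+")[[1]]
      as.numeric(v[-1])
    })
    m <- do.call(rbind, rows)
    rownames(m) <- c("A", "C", "G", "T")
    out[[strsplit(hdr, "\\s+")[[1]][1]]] <- m
  }
  out
}

#' Read and write contact maps as bin-triplet text
#'
#' Three tab-separated columns, no header: bin1_start, bin2_start, count
#' (upper triangle is sufficient; the matrix is symmetrized on read).
#'
#' @param path File path.
#' @param resolution Bin size in bp.
#' @param chrom Chromosome name for the map.
#' @param n_bins Number of bins; inferred from the largest bin if missing.
#' @return A [contact_map()].
#' @export
read_contact_triplet <- function(path, resolution, chrom = "chr1",
                                 n_bins = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("bin1", "bin2", "count"))
  i <- df$bin1 / resolution + 1
  j <- df$bin2 / resolution + 1
  if (any(i != round(i)) || any(j != round(j)))
    stop("bin starts are not multiples of the resolution")
  n <- n_bins %||% max(i, j)
  m <- matrix(0, n, n)
  m[cbind(i, j)] <- df$count
  m[cbind(j, i)] <- df$count
  contact_map(m, resolution, chrom)
}

#' @rdname read_contact_triplet
#' @param map A [contact_map()]; the upper triangle of nonzero counts is
#'   written.
#' @export
write_contact_triplet <- function(map, path) {
  stopifnot(inherits(map, "contact_map"))
  m <- map$mat
  idx <- which(upper.tri(m, diag = TRUE) & m != 0, arr.ind = TRUE)
  df <- data.frame((idx[, 1] - 1) * map$resolution,
                   (idx[, 2] - 1) * map$resolution,
                   m[idx])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write cohort tables
#'
#' A cohort table is one row per sample: `sample_id`, survival columns
#' (`time` in days, `event` 0/1), covariates (`age`, `sex`, `study`,
#' optionally `risk_group`, `lsc17`), then one numeric column per gene.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_cohort_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname read_cohort_tsv
#' @param x Cohort data frame.
#' @export
write_cohort_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
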