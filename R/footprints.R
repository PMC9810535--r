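#' Aggregate Tn5 cleavage profile around motif sites
#'
#' Sums per-base cut counts over all sites of one motif (minus-strand
#' windows are reversed so the profile is in motif orientation) and
#' normalizes to a per-base cleavage probability summing to 1 over the
#' window (motif width + 2 * flank).
#'
#' @param cut_counts Sites x window matrix of per-base cut counts; window
#'   length must equal motif width + 2 * `flank`. Rows with `NA` (windows
#'   truncated at a chromosome edge) are skipped with a message.
#' @param sites Interval data frame of the sites (for `strand`); optional.
#' @param flank Flank size in bp on each side of the motif.
#' @return List of class `"cleavage_profile"`: `profile` (per-base
#'   probability), `n_sites`, `flank`, `motif_width`.
#' @export
cleavage_profile <- function(cut_counts, sites = NULL, flank = 250) {
  stopifnot(is.matrix(cut_counts))
  L <- ncol(cut_counts)
  if (L <= 2 * flank) stop("window shorter than twice the flank")
  complete <- stats::complete.cases(cut_counts)
  if (any(!complete))
    message("skipping ", sum(!complete), " site(s) with truncated windows")
  cc <- cut_counts[complete, , drop = FALSE]
  if (!nrow(cc)) stop("no complete sites")
  if (!is.null(sites)) {
    strand <- sites$strand[complete]
    minus <- which(strand == "-")
    if (length(minus))
      cc[minus, ] <- cc[minus, rev(seq_len(L)), drop = FALSE]
  }
  total <- colSums(cc)
  if (sum(total) == 0) stop("all cut counts are zero")
  structure(list(profile = total / sum(total), n_sites = nrow(cc),
                 flank = flank, motif_width = L - 2 * flank),
            class = "cleavage_profile")
}

#' @export
print.cleavage_profile <- function(x, ...) {
  inside <- x$profile[(x$flank + 1):(x$flank + x$motif_width)]
  flankv <- x$profile[c(1:x$flank, (x$flank + x$motif_width + 1):length(x$profile))]
  cat(sprintf(
    "cleavage profile: %d sites, motif %d bp +/- %d bp; motif/flank mean ratio %.2f\n",
    x$n_sites, x$motif_width, x$flank, mean(inside) / mean(flankv)))
  invisible(x)
}

# two-sided hypergeometric p by summing point masses <= observed mass
# ("method of small p-values"); N population, K in A, n in B, k in both
hyper_p2 <- function(N, K, n, k) {
  supp <- max(0, K + n - N):min(K, n)
  d <- stats::dhyper(supp, K, N - K, n)
  d_obs <- stats::dhyper(k, K, N - K, n)
  min(1, sum(d[d <= d_obs * (1 + 1e-7)]))
}

#' TF footprint co-occurrence in cisREs
#'
#' For each TF, membership is the set of cisREs containing at least one of
#' its footprints. Each TF pair is tested for co-occurrence with a
#' two-sided hypergeometric test (population = all cisREs).
#'
#' @param footprints_by_tf Named list of interval data frames, one per TF.
#' @param cisres Interval data frame of cisREs.
#' @return List: `membership` (cisREs x TFs logical matrix), `pairs`
#'   (data frame `tf_a`, `tf_b`, `k`, `n_a`, `n_b`, `p`).
#' @export
cooccurrence <- function(footprints_by_tf, cisres) {
  if (length(footprints_by_tf) < 2) stop("need at least 2 TFs")
  if (!nrow(cisres)) stop("cisres is empty")
  gr <- as_granges(cisres)
  membership <- vapply(footprints_by_tf, function(fp)
    GenomicRanges::countOverlaps(gr, as_granges(fp), ignore.strand = TRUE) > 0,
    logical(nrow(cisres)))
  absent <- colSums(membership) == 0
  if (any(absent))
    warning("TF(s) absent from all cisREs: ",
            paste(colnames(membership)[absent], collapse = ", "))
  tfs <- colnames(membership)
  N <- nrow(cisres)
  pairs <- utils::combn(tfs, 2)
  res <- data.frame(tf_a = pairs[1, ], tf_b = pairs[2, ],
                    stringsAsFactors = FALSE)
  res$n_a <- colSums(membership)[res$tf_a]
  res$n_b <- colSums(membership)[res$tf_b]
  res$k <- vapply(seq_len(nrow(res)), function(i)
    sum(membership[, res$tf_a[i]] & membership[, res$tf_b[i]]), numeric(1))
  res$p <- vapply(seq_len(nrow(res)), function(i)
    hyper_p2(N, res$n_a[i], res$n_b[i], res$k[i]), numeric(1))
  rownames(res) <- NULL
  list(membership = membership, pairs = res)
}

# count cisREs overlapping >= 1 peak; sorted-scan, fast enough for
# thousand-fold permutation loops (half-open coordinates)
count_overlapping <- function(cisres, peaks) {
  total <- 0
  for (ch in unique(cisres$chrom)) {
    ci <- cisres$chrom == ch
    pk <- peaks$chrom == ch
    if (!any(pk)) next
    s <- peaks$start[pk]; e <- peaks$end[pk]
    o <- order(s); s <- s[o]; e <- e[o]
    # merge: disjoint sorted blocks
    if (length(s) > 1) {
      cme <- cummax(e)
      newblock <- c(TRUE, s[-1] > cme[-length(s)])
      grp <- cumsum(newblock)
      s <- s[newblock]
      e <- vapply(split(e, grp), max, numeric(1))
    }
    cs <- cisres$start[ci]; ce <- cisres$end[ci]
    j <- findInterval(ce - 0.5, s)   # last block with s < ce
    hit <- j >= 1 & e[pmax(j, 1)] > cs
    total <- total + sum(hit)
  }
  total
}

#' Occupancy enrichment of peaks in cisREs by genome permutation
#'
#' Counts the cisREs overlapping at least one peak and compares against a
#' null built by re-placing an equal number of same-length peaks uniformly
#' across the genome ([random_placement()]), `n_perm` times.
#'
#' @param cisres Interval data frame of cisREs.
#' @param peaks Interval data frame of TF peaks.
#' @param genome A [genome()].
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return List: `observed`, `perm_mean`, `perm_sd`, `z`, `p_emp`,
#'   `degenerate` (TRUE when the permutation s.d. is 0 and z is reported
#'   as 0).
#' @export
occupancy_enrichment <- function(cisres, peaks, genome, n_perm = 1000,
                                 seed = NULL) {
  if (!nrow(peaks)) stop("peaks is empty")
  validate_intervals(cisres, genome)
  validate_intervals(peaks, genome)
  obs <- count_overlapping(cisres, peaks)
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(p)
    count_overlapping(cisres, random_placement(peaks, genome)),
    numeric(1)))
  pm <- mean(perm); ps <- stats::sd(perm)
  degenerate <- is.na(ps) || ps == 0
  z <- if (degenerate) 0 else (obs - pm) / ps
  if (degenerate)
    warning("permutation distribution is degenerate; z reported as 0")
  list(observed = obs, perm_mean = pm, perm_sd = ps, z = z,
       p_emp = (1 + sum(perm >= obs)) / (n_perm + 1),
       degenerate = degenerate)
}

#' Edge-to-edge spacing between two TFs' footprints within cisREs
#'
#' For every cisRE containing footprints of both TFs, the distance is the
#' minimum over footprint pairs of the edge-to-edge gap (overlapping
#' footprints score 0).
#'
#' @param footprints_by_tf Named list of interval data frames.
#' @param cisres Interval data frame of cisREs.
#' @param tf_a,tf_b TF names (entries of `footprints_by_tf`).
#' @return List: `distances` (one per shared cisRE), `mean_distance`,
#'   `n_cisres`.
#' @export
footprint_spacing <- function(footprints_by_tf, cisres, tf_a, tf_b) {
  fa <- footprints_by_tf[[tf_a]]; fb <- footprints_by_tf[[tf_b]]
  if (is.null(fa) || is.null(fb)) stop("unknown TF name")
  gr <- as_granges(cisres)
  hits_a <- GenomicRanges::findOverlaps(gr, as_granges(fa),
                                        ignore.strand = TRUE)
  hits_b <- GenomicRanges::findOverlaps(gr, as_granges(fb),
                                        ignore.strand = TRUE)
  a_by <- split(S4Vectors::subjectHits(hits_a), S4Vectors::queryHits(hits_a))
  b_by <- split(S4Vectors::subjectHits(hits_b), S4Vectors::queryHits(hits_b))
  shared <- intersect(names(a_by), names(b_by))
  if (!length(shared)) stop("no cisRE contains footprints of both TFs")
  d <- vapply(shared, function(ci) {
    ia <- a_by[[ci]]; ib <- b_by[[ci]]
    gaps <- outer(seq_along(ia), seq_along(ib), function(x, y)
      pmax(0, pmax(fa$start[ia[x]], fb$start[ib[y]]) -
             pmin(fa$end[ia[x]], fb$end[ib[y]])))
    min(gaps)
  }, numeric(1))
  list(distances = unname(d), mean_distance = mean(d),
       n_cisres = length(d))
}

#' Paired signal contrast between cell types on shared footprints
#'
#' Wilcoxon signed-rank tests of normalized signal on the same footprints
#' between a reference cell type and each other cell type (two-sided).
#' The signal matrix is also returned sorted by footprint occupancy
#' posterior (descending) for heatmap display.
#'
#' @param signal Footprints x cell types numeric matrix.
#' @param reference Reference cell type (column name).
#' @param posterior Optional per-footprint occupancy posterior used for
#'   sorting.
#' @return List: `tests` (data frame `cell_type`, `statistic`, `p`),
#'   `sorted_signal`.
#' @export
signal_contrast <- function(signal, reference, posterior = NULL) {
  stopifnot(is.matrix(signal), reference %in% colnames(signal))
  others <- setdiff(colnames(signal), reference)
  ref <- signal[, reference]
  tests <- do.call(rbind, lapply(others, function(ct) {
    x <- signal[, ct]
    if (all(x - ref == 0))
      return(data.frame(cell_type = ct, statistic = NA_real_, p = 1))
    wt <- stats::wilcox.test(x, ref, paired = TRUE)
    data.frame(cell_type = ct, statistic = unname(wt$statistic),
               p = wt$p.value, stringsAsFactors = FALSE)
  }))
  sorted <- signal
  if (!is.null(posterior))
    sorted <- signal[order(posterior, decreasing = TRUE), , drop = FALSE]
  list(tests = tests, sorted_signal = sorted)
}

#' @export
plot.cleavage_profile <- function(x, ...) {
  pos <- seq_along(x$profile) - x$flank - 1
  graphics::plot(pos, x$profile, type = "l",
                 xlab = "position relative to motif start (bp)",
                 ylab = "cleavage probability",
                 main = sprintf("%d sites", x$n_sites), ...)
  graphics::abline(v = c(0, x$motif_width), lty = 2, col = "grey50")
  invisible(x)
}
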