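#' Build a cis-regulatory element catalog from per-population peak sets
#'
#' The catalog is the merged union of all populations' accessibility
#' peaks; each catalog element is annotated with the populations whose
#' peaks overlap it.
#'
#' @param peak_sets Named list of interval data frames, one per
#'   population.
#' @return List: `cisres` (interval data frame with a `cisre_id` column)
#'   and `membership` (logical cisREs x populations matrix).
#' @export
build_cisre_catalog <- function(peak_sets) {
  if (!length(peak_sets)) stop("no peak sets supplied")
  stopifnot(!is.null(names(peak_sets)))
  cisres <- merge_intervals(do.call(rbind, lapply(peak_sets, function(x)
    x[c("chrom", "start", "end")])))
  cisres$cisre_id <- sprintf("cisre_%05d", seq_len(nrow(cisres)))
  gr <- as_granges(cisres)
  membership <- vapply(peak_sets, function(p)
    GenomicRanges::countOverlaps(gr, as_granges(p), ignore.strand = TRUE) > 0,
    logical(nrow(cisres)))
  if (is.null(dim(membership)))
    membership <- matrix(membership, nrow = nrow(cisres),
                         dimnames = list(NULL, names(peak_sets)))
  rownames(membership) <- cisres$cisre_id
  list(cisres = cisres, membership = membership)
}

#' Score cisRE-gene links from accessibility and expression
#'
#' Candidate pairs are (cisRE, gene) with the cisRE midpoint within
#' `window_bp` of the gene's TSS. The link statistic is the Pearson
#' correlation of accessibility and expression across the shared,
#' ordered cell populations. The empirical null is built from trans
#' pairs — random cisRE x gene combinations on different chromosomes —
#' giving a one-sided empirical p for positive association, adjusted by
#' Benjamini-Hochberg.
#'
#' @param accessibility cisREs x populations matrix (rownames =
#'   `cisre_id`).
#' @param cisres Interval data frame with `cisre_id` matching the
#'   accessibility rows.
#' @param expression Genes x populations matrix over the same ordered
#'   populations.
#' @param tss Data frame `gene`, `chrom`, `pos`, `strand`.
#' @param window_bp TSS window for candidate pairs.
#' @param n_perm Number of trans-pair null draws.
#' @param seed Integer seed.
#' @return Data frame of links: `cisre_id`, `gene`, `distance_bp`, `r`,
#'   `p_emp`, `q`.
#' @export
score_links <- function(accessibility, cisres, expression, tss,
                        window_bp = 500000, n_perm = 1000, seed = NULL) {
  stopifnot(ncol(accessibility) == ncol(expression))
  if (!is.null(colnames(accessibility)) && !is.null(colnames(expression)) &&
      !identical(colnames(accessibility), colnames(expression)))
    stop("accessibility and expression must share the same ordered populations")
  stopifnot(all(tss$gene %in% rownames(expression)))
  mid <- (cisres$start + cisres$end) / 2
  # candidates per gene
  cand <- do.call(rbind, lapply(seq_len(nrow(tss)), function(g) {
    same <- cisres$chrom == tss$chrom[g]
    d <- mid - tss$pos[g]
    hit <- same & abs(d) <= window_bp
    if (!any(hit)) return(NULL)
    data.frame(cisre_id = cisres$cisre_id[hit], gene = tss$gene[g],
               distance_bp = d[hit], stringsAsFactors = FALSE)
  }))
  if (is.null(cand) || nrow(cand) == 0)
    return(data.frame(cisre_id = character(), gene = character(),
                      distance_bp = numeric(), r = numeric(),
                      p_emp = numeric(), q = numeric()))
  A <- accessibility[cand$cisre_id, , drop = FALSE]
  E <- expression[cand$gene, , drop = FALSE]
  sd_a <- apply(A, 1, stats::sd); sd_e <- apply(E, 1, stats::sd)
  const <- sd_a == 0 | sd_e == 0
  if (any(const))
    message("skipping ", sum(const), " link(s) with constant vectors")
  cand <- cand[!const, , drop = FALSE]
  A <- A[!const, , drop = FALSE]; E <- E[!const, , drop = FALSE]
  if (nrow(cand) == 0)
    return(data.frame(cisre_id = character(), gene = character(),
                      distance_bp = numeric(), r = numeric(),
                      p_emp = numeric(), q = numeric()))
  rowcor <- function(X, Y) {
    X <- X - rowMeans(X); Y <- Y - rowMeans(Y)
    rowSums(X * Y) / sqrt(rowSums(X^2) * rowSums(Y^2))
  }
  cand$r <- rowcor(A, E)

  # trans-pair empirical null
  cisre_chrom <- cisres$chrom[match(rownames(accessibility), cisres$cisre_id)]
  gene_chrom <- tss$chrom[match(rownames(expression), tss$gene)]
  if (length(unique(cisres$chrom)) < 2 &&
      length(unique(tss$chrom)) < 2 &&
      unique(cisres$chrom)[1] == unique(tss$chrom)[1])
    stop("trans-pair null requires features on more than one chromosome")
  null_r <- with_seed(seed, {
    out <- numeric(n_perm)
    got <- 0
    tries <- 0
    while (got < n_perm) {
      tries <- tries + 1
      if (tries > 1000)
        stop("could not assemble enough trans null pairs")
      m <- (n_perm - got) * 2
      ci <- sample.int(nrow(accessibility), m, replace = TRUE)
      gi <- sample.int(nrow(expression), m, replace = TRUE)
      ok <- which(!is.na(gene_chrom[gi]) & cisre_chrom[ci] != gene_chrom[gi])
      ok <- ok[seq_len(min(length(ok), n_perm - got))]
      if (!length(ok)) next
      a <- accessibility[ci[ok], , drop = FALSE]
      e <- expression[gi[ok], , drop = FALSE]
      r <- rowcor(a, e)
      r <- r[is.finite(r)]
      if (!length(r)) next
      out[got + seq_along(r)] <- r
      got <- got + length(r)
    }
    out
  })
  cand$p_emp <- (1 + vapply(cand$r, function(r) sum(null_r >= r),
                            numeric(1))) / (n_perm + 1)
  cand$q <- stats::p.adjust(cand$p_emp, method = "BH")
  rownames(cand) <- NULL
  cand
}

#' Select the HSC-specific regulatory network
#'
#' Weighs each significant link by the cisRE's accessibility in HSCs:
#' `hememap_score = r * minmax(HSC accessibility)`. Links are retained
#' when significant (`q < q_thresh`) and open in HSCs; the network gene
#' list contains every gene with at least one retained link.
#'
#' @param links Data frame from [score_links()].
#' @param hsc_accessibility Named per-cisRE accessibility in the HSC
#'   population.
#' @param q_thresh FDR threshold.
#' @return List: `links` (retained, with `hememap_score`), `genes`.
#' @export
select_hsc_network <- function(links, hsc_accessibility, q_thresh = 0.05) {
  acc <- hsc_accessibility[links$cisre_id]
  acc_scaled <- minmax(acc)
  links$hsc_accessibility <- as.numeric(acc)
  links$hememap_score <- links$r * acc_scaled
  keep <- !is.na(acc) & links$q < q_thresh & acc > 0
  list(links = links[keep, , drop = FALSE],
       genes = unique(links$gene[keep]))
}

# reverse complement of a PFM: reverse columns, swap A<->T and C<->G
pfm_revcomp <- function(m) {
  m[c("T", "G", "C", "A"), rev(seq_len(ncol(m))), drop = FALSE]
}

pfm_normalize <- function(m) {
  stopifnot(nrow(m) == 4)
  if (is.null(rownames(m))) rownames(m) <- c("A", "C", "G", "T")
  cs <- colSums(m)
  if (any(cs <= 0)) stop("PFM has non-positive column sums")
  sweep(m, 2, cs, "/")
}

# best Pearson correlation between two PFMs over all offsets/orientations
pfm_best_cor <- function(fa, fb, min_overlap) {
  best <- -Inf; best_off <- NA_integer_; best_orient <- NA_character_
  any_defined <- FALSE
  for (orient in c("forward", "revcomp")) {
    b <- if (orient == "forward") fb else pfm_revcomp(fb)
    wa <- ncol(fa); wb <- ncol(b)
    for (off in -(wb - min_overlap):(wa - min_overlap)) {
      ia <- max(1, 1 + off):min(wa, wb + off)
      ib <- ia - off
      if (length(ia) < min_overlap) next
      va <- as.numeric(fa[, ia, drop = FALSE])
      vb <- as.numeric(b[, ib, drop = FALSE])
      if (stats::sd(va) == 0 || stats::sd(vb) == 0) next
      any_defined <- TRUE
      r <- stats::cor(va, vb)
      if (r > best) { best <- r; best_off <- off; best_orient <- orient }
    }
  }
  if (!any_defined) return(NULL)
  list(best_r = best, offset = best_off, orientation = best_orient)
}

#' Motif similarity by position-frequency-matrix correlation
#'
#' Column-normalizes both PFMs, slides one against the other over every
#' offset with at least `min_overlap` overlapping columns in both
#' orientations (forward and reverse complement), and reports the best
#' Pearson correlation of the flattened overlapping columns. Significance
#' comes from a column-shuffling permutation null on the second motif.
#'
#' @param a,b 4 x w count or frequency matrices (rows A, C, G, T).
#' @param min_overlap Minimum overlapping columns.
#' @param n_perm Number of column shuffles.
#' @param seed Integer seed.
#' @return List: `best_r`, `offset`, `orientation`, `p_perm`.
#' @export
motif_similarity <- function(a, b, min_overlap = 5, n_perm = 1000,
                             seed = NULL) {
  if (ncol(a) < min_overlap || ncol(b) < min_overlap)
    stop("motif width below min_overlap")
  fa <- pfm_normalize(a); fb <- pfm_normalize(b)
  obs <- pfm_best_cor(fa, fb, min_overlap)
  if (is.null(obs))
    stop("correlation undefined: a motif has zero variance at every offset")
  null_best <- with_seed(seed, vapply(seq_len(n_perm), function(p) {
    bs <- fb[, sample.int(ncol(fb)), drop = FALSE]
    res <- pfm_best_cor(fa, bs, min_overlap)
    if (is.null(res)) NA_real_ else res$best_r
  }, numeric(1)))
  null_best <- null_best[!is.na(null_best)]
  obs$p_perm <- (1 + sum(null_best >= obs$best_r)) / (length(null_best) + 1)
  obs
}
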