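#' Log-normalize a single-cell count matrix
#'
#' Library-size normalization followed by a log2 transform:
#' `log2(1 + count / libsize * scale)`. With the default
#' `scale = 1e4` the transformed unit is log2(1 + CPM/100). Cells with a
#' zero total count are dropped with a message.
#'
#' @param counts Cells x genes non-negative matrix.
#' @param scale Counts-per-unit scale factor.
#' @return Normalized cells x genes matrix; dropped cell count is attached
#'   as attribute `"dropped_cells"`.
#' @export
normalize_log <- function(counts, scale = 1e4) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  lib <- rowSums(counts)
  drop <- lib == 0
  if (any(drop)) {
    message("excluding ", sum(drop), " cell(s) with zero total counts")
    counts <- counts[!drop, , drop = FALSE]
    lib <- lib[!drop]
  }
  out <- log2(1 + counts / lib * scale)
  attr(out, "dropped_cells") <- sum(drop)
  out
}

# Vectorized two-part hurdle statistics for all genes at once.
# Y: cells x genes normalized values; Z = (Y > 0); Y2 = Y^2 precomputed.
# m1: 0/1 numeric mask of group A cells. Returns a data.frame.
hurdle_stats <- function(Y, Y2, Z, m1, min_frac) {
  n1 <- sum(m1); n2 <- nrow(Y) - n1
  m1 <- as.numeric(m1)
  k1 <- drop(crossprod(Z, m1)); ktot <- colSums(Z); k2 <- ktot - k1
  s1 <- drop(crossprod(Y, m1)); stot <- colSums(Y); s2 <- stot - s1
  ss1 <- drop(crossprod(Y2, m1)); sstot <- colSums(Y2); ss2 <- sstot - ss1

  detect1 <- k1 / n1; detect2 <- k2 / n2
  tested <- detect1 >= min_frac | detect2 >= min_frac

  # discrete part: Bernoulli detection LRT (1 df)
  bll <- function(k, n) {
    p <- k / n
    out <- numeric(length(k))
    pos <- k > 0; out[pos] <- out[pos] + k[pos] * log(p[pos])
    neg <- k < n; out[neg] <- out[neg] + (n - k[neg]) * log(1 - p[neg])
    out
  }
  lr_d <- 2 * (bll(k1, n1) + bll(k2, n2) - bll(k1 + k2, n1 + n2))

  # continuous part: Gaussian on nonzero values, shared variance (1 df);
  # drops to 0 df when either group has no detected cells
  rss1 <- pmax(ss1 - s1^2 / pmax(k1, 1), 0)
  rss2 <- pmax(ss2 - s2^2 / pmax(k2, 1), 0)
  kc <- k1 + k2
  rss_alt <- rss1 + rss2
  rss_null <- pmax(ss1 + ss2 - (s1 + s2)^2 / pmax(kc, 1), 0)
  cont_ok <- k1 >= 1 & k2 >= 1 & kc >= 3
  lr_c <- numeric(length(k1))
  idx <- cont_ok & rss_alt > 1e-12
  lr_c[idx] <- kc[idx] * log(rss_null[idx] / rss_alt[idx])
  # all nonzero values identical within groups but not across: saturate
  sep <- cont_ok & rss_alt <= 1e-12 & rss_null > 1e-12
  lr_c[sep] <- Inf

  df <- 1 + as.numeric(cont_ok)
  lr <- pmax(lr_d, 0) + pmax(lr_c, 0)
  p <- stats::pchisq(lr, df = df, lower.tail = FALSE)
  data.frame(gene = colnames(Y) %||% as.character(seq_along(k1)),
             log2fc = s1 / n1 - s2 / n2,
             p = p,
             detect_rate_a = detect1, detect_rate_b = detect2,
             tested = tested, stringsAsFactors = FALSE)
}

#' Two-part hurdle differential expression test
#'
#' Per-gene likelihood-ratio test combining a Bernoulli component on the
#' detection indicator and a Gaussian component on the log-normalized
#' nonzero values (shared variance), referred to a chi-square with 2
#' degrees of freedom (1 when a gene is detected in only one group, where
#' the continuous component degenerates). This is the hurdle principle
#' behind MAST-style single-cell DE testing, without the cellular detection
#' rate covariate.
#'
#' The log2 fold change is the difference of group means of the normalized
#' values, oriented `ref_level` minus the other group (genes higher in the
#' reference/control group have positive `log2fc`). Genes are tested only
#' if detected in at least `min_frac` of cells in either group; Bonferroni
#' adjustment is over tested genes.
#'
#' @param norm Normalized cells x genes matrix (see [normalize_log()]).
#' @param groups Factor/vector of two group labels per cell.
#' @param ref_level Reference group (orientation of `log2fc`); default =
#'   first factor level.
#' @param min_frac Detection fraction required in at least one group.
#' @return Data frame of tested genes: `gene`, `log2fc`, `p`, `adj_p`,
#'   `detect_rate_a`, `detect_rate_b`; attributes `n_tested`, `ref_level`.
#' @export
hurdle_de <- function(norm, groups, ref_level = NULL, min_frac = 0.05) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) != 2)
    stop("exactly two groups are required")
  groups <- droplevels(groups)
  if (length(groups) != nrow(norm))
    stop("groups must have one label per cell (row)")
  if (min(table(groups)) < 2) stop("each group needs at least 2 cells")
  ref_level <- ref_level %||% levels(groups)[1]
  if (!ref_level %in% levels(groups)) stop("unknown ref_level")
  m1 <- as.numeric(groups == ref_level)
  res <- hurdle_stats(norm, norm^2, (norm > 0) * 1, m1, min_frac)
  res <- res[res$tested, setdiff(names(res), "tested"), drop = FALSE]
  res$adj_p <- pmin(1, res$p * nrow(res))
  rownames(res) <- NULL
  attr(res, "n_tested") <- nrow(res)
  attr(res, "ref_level") <- ref_level
  res
}

#' Call network gene sets from differential expression results
#'
#' With the reference-minus-perturbed orientation of [hurdle_de()], the
#' "down" set contains genes significantly higher in the reference
#' (i.e. downregulated after perturbation) and the "up" set the converse.
#'
#' @param de Data frame from [hurdle_de()].
#' @param fc_thresh Absolute log2 fold-change threshold.
#' @param p_thresh Adjusted-p threshold.
#' @return List of class `"network_gene_sets"`: `down`, `up` (character
#'   vectors) and `orientation`.
#' @export
call_network <- function(de, fc_thresh = 0.05, p_thresh = 1e-20) {
  if (is.null(de) || nrow(de) == 0)
    return(structure(list(down = character(), up = character(),
                          orientation = attr(de, "ref_level") %||% NA_character_),
                     class = "network_gene_sets"))
  sig <- de$adj_p < p_thresh
  structure(list(down = de$gene[sig & de$log2fc > fc_thresh],
                 up = de$gene[sig & de$log2fc < -fc_thresh],
                 orientation = attr(de, "ref_level") %||% NA_character_),
            class = "network_gene_sets")
}

#' @export
print.network_gene_sets <- function(x, ...) {
  cat(sprintf("network gene sets (reference = %s): %d down, %d up\n",
              x$orientation, length(x$down), length(x$up)))
  invisible(x)
}

#' Permutation null for differential-expression discovery
#'
#' Shuffles the group labels and records how many genes pass the network
#' thresholds in each permutation. On exchangeable data this should be zero
#' at stringent thresholds.
#'
#' @inheritParams hurdle_de
#' @param n_perm Number of label permutations.
#' @param seed Integer seed.
#' @inheritParams call_network
#' @return Integer vector (length `n_perm`) of `down + up` set sizes.
#' @export
permutation_de_null <- function(norm, groups, n_perm = 100, seed = NULL,
                                fc_thresh = 0.05, p_thresh = 1e-20,
                                min_frac = 0.05) {
  groups <- droplevels(as.factor(groups))
  stopifnot(nlevels(groups) == 2)
  Y2 <- norm^2
  Z <- (norm > 0) * 1
  n1 <- sum(groups == levels(groups)[1])
  with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      m1 <- numeric(nrow(norm))
      m1[sample.int(nrow(norm), n1)] <- 1
      res <- hurdle_stats(norm, Y2, Z, m1, min_frac)
      res <- res[res$tested, , drop = FALSE]
      adj <- pmin(1, res$p * nrow(res))
      sum(adj < p_thresh & abs(res$log2fc) > fc_thresh)
    }, integer(1))
  })
}

#' Pseudobulk concordance of single-cell fold changes
#'
#' Aggregates raw counts per group into pseudobulk profiles, computes the
#' pseudobulk log2 fold change on CPM-log scale, and measures Spearman
#' concordance with the single-cell fold changes. Significance comes from
#' a cell-label permutation null (one-sided, positive concordance).
#'
#' @param counts Raw cells x genes count matrix.
#' @param groups Two group labels per cell.
#' @param sc_log2fc Named per-gene single-cell log2 fold changes (only the
#'   genes that passed the single-cell detection cutoff).
#' @param ref_level Reference group, matching the single-cell orientation.
#' @param n_perm Number of label permutations.
#' @param seed Integer seed.
#' @param scale CPM scale for the pseudobulk transform.
#' @return List: `pb_log2fc` (named vector), `rho`, `p_perm`, `n_genes`.
#' @export
pseudobulk_concordance <- function(counts, groups, sc_log2fc,
                                   ref_level = NULL, n_perm = 1000,
                                   seed = NULL, scale = 1e6) {
  groups <- droplevels(as.factor(groups))
  stopifnot(nlevels(groups) == 2)
  ref_level <- ref_level %||% levels(groups)[1]
  genes <- intersect(names(sc_log2fc), colnames(counts))
  if (length(genes) < 3) stop("fewer than 3 shared genes")
  cnt <- counts[, genes, drop = FALSE]
  pb_lfc <- function(m1) {
    a <- colSums(cnt[m1, , drop = FALSE]); b <- colSums(cnt[!m1, , drop = FALSE])
    log2(1 + a / sum(a) * scale) - log2(1 + b / sum(b) * scale)
  }
  m1 <- groups == ref_level
  obs <- pb_lfc(m1)
  rho <- stats::cor(obs, sc_log2fc[genes], method = "spearman")
  null_rho <- with_seed(seed, vapply(seq_len(n_perm), function(p) {
    mp <- logical(length(m1)); mp[sample.int(length(m1), sum(m1))] <- TRUE
    stats::cor(pb_lfc(mp), sc_log2fc[genes], method = "spearman")
  }, numeric(1)))
  list(pb_log2fc = obs, rho = rho,
       p_perm = (1 + sum(null_rho >= rho)) / (n_perm + 1),
       n_genes = length(genes))
}

#' Per-cell gene-signature score
#'
#' Each signature gene's log-normalized expression is min-max scaled to
#' \code{[0, 1]} across cells and the per-cell score is the mean over the
#' signature; cells above `cutoff` are called signature-high. The default
#' signature is the HSC marker trio CD34/HLF/CRHBP.
#'
#' @param norm Normalized cells x genes matrix.
#' @param signature Character vector of signature genes.
#' @param cutoff Score threshold for the high call.
#' @return Data frame: `cell`, `score`, `call`.
#' @export
signature_score <- function(norm, signature = c("CD34", "HLF", "CRHBP"),
                            cutoff = 0.5) {
  missing <- setdiff(signature, colnames(norm))
  if (length(missing))
    stop("signature gene(s) missing from matrix: ",
         paste(missing, collapse = ", "))
  scaled <- apply(norm[, signature, drop = FALSE], 2, minmax)
  if (is.null(dim(scaled))) scaled <- matrix(scaled, nrow = 1)
  score <- rowMeans(scaled)
  data.frame(cell = rownames(norm) %||% as.character(seq_len(nrow(norm))),
             score = score, call = score > cutoff,
             stringsAsFactors = FALSE, row.names = NULL)
}
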