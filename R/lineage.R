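#' Permutation z-score for gene-set enrichment across cell types
#'
#' For each cell type (column) the observed statistic is the mean
#' expression of the tested gene set; random gene sets of the same size are
#' drawn from all genes in the matrix, and the enrichment z-score is
#' `(y_obs - mean(y_perm)) / sd(y_perm)` with moments taken per cell type
#' over the permutation draws. One permuted set is scored on all columns,
#' so draws are shared across cell types within a call.
#'
#' When the number of same-size subsets `choose(n_genes, |set|)` is at most
#' `exhaustive_limit`, all subsets are enumerated instead of sampled
#' (exact permutation moments).
#'
#' @param profiles Genes x cell types numeric matrix (log2-normalized
#'   units), rownames = genes.
#' @param gene_set Character vector, a strict non-empty subset of the rows.
#' @param n_perm Number of Monte-Carlo permutations.
#' @param seed Integer seed.
#' @param exhaustive `TRUE`/`FALSE` to force/disable enumeration; `NULL`
#'   auto-enables when feasible.
#' @param exhaustive_limit Subset-count limit for auto enumeration.
#' @param match_expression If `TRUE`, permuted genes are sampled within
#'   deciles of overall mean expression (sensitivity analysis).
#' @return Data frame, one row per cell type: `cell_type`, `y_obs`,
#'   `perm_mean`, `perm_sd`, `z`, `degenerate` (TRUE where `perm_sd` was 0
#'   and `z` was set to 0 with a warning).
#' @export
lineage_zscore <- function(profiles, gene_set, n_perm = 1000, seed = NULL,
                           exhaustive = NULL, exhaustive_limit = 10000,
                           match_expression = FALSE) {
  stopifnot(is.matrix(profiles), !is.null(rownames(profiles)))
  genes <- rownames(profiles)
  if (!all(gene_set %in% genes))
    stop("gene_set contains genes absent from the profile matrix")
  k <- length(unique(gene_set))
  if (k == 0 || k >= length(genes))
    stop("gene_set must be a non-empty strict subset of the matrix genes")
  gene_set <- unique(gene_set)
  y_obs <- colMeans(profiles[gene_set, , drop = FALSE])

  n <- length(genes)
  do_exhaustive <- exhaustive %||% (choose(n, k) <= exhaustive_limit)
  if (do_exhaustive && choose(n, k) > 1e6)
    stop("exhaustive enumeration infeasible for choose(", n, ", ", k, ") subsets")
  if (do_exhaustive) {
    sets <- utils::combn(n, k)
    perm_means <- t(apply(sets, 2, function(idx)
      colMeans(profiles[idx, , drop = FALSE])))
  } else if (match_expression) {
    overall <- rowMeans(profiles)
    dec <- cut(rank(overall, ties.method = "first"),
               breaks = 10, labels = FALSE)
    by_dec <- split(seq_len(n), dec)
    set_dec <- dec[match(gene_set, genes)]
    need <- table(factor(set_dec, levels = names(by_dec)))
    perm_means <- with_seed(seed, t(vapply(seq_len(n_perm), function(p) {
      idx <- unlist(lapply(names(by_dec), function(d) {
        m <- need[[d]]
        if (m == 0) integer() else
          by_dec[[d]][sample.int(length(by_dec[[d]]), m)]
      }), use.names = FALSE)
      colMeans(profiles[idx, , drop = FALSE])
    }, numeric(ncol(profiles)))))
  } else {
    perm_means <- with_seed(seed, t(vapply(seq_len(n_perm), function(p)
      colMeans(profiles[sample.int(n, k), , drop = FALSE]),
      numeric(ncol(profiles)))))
  }
  if (ncol(profiles) == 1) perm_means <- matrix(perm_means, ncol = 1)

  pm <- colMeans(perm_means)
  # permutation s.d. over all draws P (population form matches the
  # exhaustive enumeration exactly)
  psd <- sqrt(colMeans(perm_means^2) - pm^2)
  psd[psd < 0] <- 0
  degenerate <- psd <= .Machine$double.eps^0.5 * pmax(1, abs(pm))
  z <- ifelse(degenerate, 0, (y_obs - pm) / psd)
  if (any(degenerate))
    warning("permutation s.d. is zero for ", sum(degenerate),
            " cell type(s); z reported as 0")
  data.frame(cell_type = colnames(profiles) %||%
               as.character(seq_len(ncol(profiles))),
             y_obs = y_obs, perm_mean = pm, perm_sd = psd, z = z,
             degenerate = degenerate, row.names = NULL,
             stringsAsFactors = FALSE)
}
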