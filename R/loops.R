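#' Binned chromatin contact map
#'
#' A per-chromosome symmetric matrix of interaction counts at fixed
#' resolution. Bin `i` covers `[(i-1) * resolution, i * resolution)`.
#' Balancing weights (from [kr_balance()]) are stored per bin; masked bins
#' carry `NA` weights.
#'
#' @param mat Symmetric non-negative numeric matrix.
#' @param resolution Bin size in bp.
#' @param chrom Chromosome name.
#' @param weights Optional per-bin balancing weights.
#' @return Object of class `"contact_map"`.
#' @export
contact_map <- function(mat, resolution, chrom = "chr1", weights = NULL) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  if (any(mat < 0)) stop("contact counts must be non-negative")
  if (max(abs(mat - t(mat))) > 1e-8 * max(1, max(mat)))
    stop("contact matrix must be symmetric")
  structure(list(mat = mat, resolution = resolution, chrom = chrom,
                 weights = weights, n_bins = nrow(mat)),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("contact_map: %s, %d bins @ %s bp, %s\n", x$chrom, x$n_bins,
              format(x$resolution, big.mark = ","),
              if (is.null(x$weights)) "unbalanced" else "balanced"))
  invisible(x)
}

#' Balanced interaction matrix
#'
#' Returns `diag(w) %*% M %*% diag(w)` for a balanced map; masked bins are
#' zero.
#'
#' @param map A balanced [contact_map()].
#' @return Numeric matrix.
#' @export
balanced_matrix <- function(map) {
  stopifnot(inherits(map, "contact_map"))
  if (is.null(map$weights)) stop("map has no balancing weights; run kr_balance()")
  w <- map$weights
  w[is.na(w)] <- 0
  map$mat * outer(w, w)
}

# Knight-Ruiz balancing: Newton inner iteration with conjugate-gradient
# steps (Knight & Ruiz 2013, alg. "bnewt"). A is symmetric nonneg with
# total support on the unmasked rows; returns x with (x * A %*% x) ~ 1.
kr_core <- function(A, tol = 1e-6, delta = 0.1, Delta = 3, max_outer = 3000) {
  n <- nrow(A)
  e <- rep(1, n)
  x <- e
  g <- 0.9; etamax <- 0.1; eta <- etamax; stop_tol <- tol * 0.5
  rt <- tol^2
  v <- x * drop(A %*% x)
  rk <- 1 - v
  rho_km1 <- sum(rk * rk)
  rout <- rho_km1; rold <- rout
  outer_it <- 0
  while (rout > rt) {
    outer_it <- outer_it + 1
    if (outer_it > max_outer) return(NULL)
    k <- 0; y <- e
    innertol <- max(eta^2 * rout, rt)
    rho_km2 <- rho_km1
    Z <- p <- NULL
    while (rho_km1 > innertol) {
      k <- k + 1
      if (k == 1) {
        Z <- rk / v
        p <- Z
        rho_km1 <- sum(rk * Z)
      } else {
        beta <- rho_km1 / rho_km2
        p <- Z + beta * p
      }
      w <- x * drop(A %*% (x * p)) + v * p
      alpha <- rho_km1 / sum(p * w)
      ap <- alpha * p
      ynew <- y + ap
      if (min(ynew) <= delta) {
        if (delta == 0) break
        ind <- ap < 0
        gamma <- min((delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      if (max(ynew) >= Delta) {
        ind <- ynew > Delta
        gamma <- min((Delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      y <- ynew
      rk <- rk - alpha * w
      rho_km2 <- rho_km1
      Z <- rk / v
      rho_km1 <- sum(rk * Z)
      if (k > 50) break
    }
    x <- x * y
    v <- x * drop(A %*% x)
    rk <- 1 - v
    rho_km1 <- sum(rk * rk)
    rout <- rho_km1
    rat <- rout / rold; rold <- rout
    res_norm <- sqrt(rout)
    eta_o <- eta
    eta <- g * rat
    if (g * eta_o^2 > 0.1) eta <- max(eta, g * eta_o^2)
    eta <- max(min(eta, etamax), stop_tol / res_norm)
  }
  x
}

# symmetric Sinkhorn fallback: w <- sqrt(w / (A %*% w)) iterated
sinkhorn_core <- function(A, tol = 1e-6, max_iter = 5000) {
  n <- nrow(A)
  w <- rep(1, n)
  for (i in seq_len(max_iter)) {
    r <- w * drop(A %*% w)
    if (max(abs(r - 1)) < tol) return(w)
    w <- w / sqrt(r)
  }
  r <- w * drop(A %*% w)
  if (max(abs(r - 1)) < tol * 10) return(w)
  NULL
}

#' Knight-Ruiz balancing of a contact map
#'
#' Scales a symmetric contact matrix to `B = diag(w) M diag(w)` with all
#' unmasked row sums equal (to 1). Sparse rows (< `min_nnz` nonzero
#' entries) are masked before balancing, as is standard for Hi-C/Low-C
#' maps. Uses the Knight-Ruiz Newton iteration; if it stalls, an iterated
#' proportional scaling fallback is attempted (and reported via a message).
#'
#' @param map A [contact_map()].
#' @param tol Convergence tolerance on the row sums of the balanced matrix.
#' @param max_iter Maximum outer iterations.
#' @param min_nnz Minimum nonzero entries for a row to be balanced.
#' @return The map with `weights` filled in (`NA` for masked bins).
#' @export
kr_balance <- function(map, tol = 1e-6, max_iter = 3000, min_nnz = 10) {
  stopifnot(inherits(map, "contact_map"))
  M <- map$mat
  nnz <- rowSums(M > 0)
  keep <- nnz >= min_nnz
  if (!any(keep)) stop("contact matrix has no rows with >= min_nnz nonzeros")
  A <- M[keep, keep, drop = FALSE]
  if (all(A == 0)) stop("contact matrix is entirely zero after masking")
  # scale so entries are O(1); undo afterwards (weights absorb the scale)
  sc <- mean(rowSums(A))
  A1 <- A / sc
  x <- kr_core(A1, tol = tol, max_outer = max_iter)
  if (is.null(x)) {
    message("Knight-Ruiz iteration stalled; falling back to iterative proportional scaling")
    x <- sinkhorn_core(A1, tol = tol)
  }
  if (is.null(x))
    stop("matrix balancing did not converge within the iteration limit")
  resid <- max(abs(x * drop(A1 %*% x) - 1))
  if (resid > tol * 100)
    stop("matrix balancing did not converge (residual ", signif(resid, 3), ")")
  w <- rep(NA_real_, map$n_bins)
  w[keep] <- x / sqrt(sc)
  map$weights <- w
  map
}

#' Aggregate peak analysis (APA)
#'
#' Averages balanced contact submatrices centered on loop anchor pairs and
#' summarizes focal enrichment as the peak-to-lower-left ratio (P2LL): the
#' center bin divided by the mean of the lower-left corner box (the corner
#' nearest the diagonal). With the default 25-kb resolution and
#' `window_bins = 10`, the aggregate covers +/- 250 kb (a 21 x 21 matrix)
#' and the corner is 6 x 6 (36 bins).
#'
#' Rows of the aggregate follow anchor-1 offsets (downstream increasing
#' downward), columns anchor-2 offsets (downstream increasing rightward).
#' Loops whose neighborhood crosses the diagonal or the matrix edge are
#' excluded.
#'
#' By default the balanced matrix is distance-normalized
#' (observed/expected per diagonal, expectation over unmasked bins)
#' before aggregation, so that the decay gradient between the center and
#' the diagonal-proximal corner cancels and P2LL is 1 in the absence of
#' focal enrichment.
#'
#' @param map A balanced [contact_map()].
#' @param loops Data frame with `chrom1,start1,end1,chrom2,start2,end2`
#'   (anchor 1 upstream of anchor 2).
#' @param window_bins Half-width of the aggregate window in bins.
#' @param corner Corner box size in bins.
#' @param normalize `"oe"` (observed/expected, default) or `"balanced"`
#'   (raw balanced values).
#' @return Object of class `"apa_result"`: list with `agg`, `p2ll`,
#'   `n_loops_used`, `n_excluded`, `corner_values`.
#' @export
apa <- function(map, loops, window_bins = 10, corner = 6,
                normalize = c("oe", "balanced")) {
  stopifnot(inherits(map, "contact_map"))
  normalize <- match.arg(normalize)
  B <- balanced_matrix(map)
  n <- nrow(B)
  if (normalize == "oe") {
    unmasked <- !is.na(map$weights)
    d <- abs(row(B) - col(B))
    ok <- which(outer(unmasked, unmasked, "&"))
    em <- tapply(B[ok], d[ok], mean)
    expected <- rep(NA_real_, n)
    expected[as.integer(names(em)) + 1] <- em
    ed <- matrix(expected[d + 1], n, n)
    bad <- is.na(ed) | ed == 0
    ed[bad] <- 1
    B <- B / ed
    B[bad] <- 0
  }
  W <- window_bins
  res <- map$resolution
  mid1 <- (loops$start1 + loops$end1) / 2
  mid2 <- (loops$start2 + loops$end2) / 2
  i <- floor(mid1 / res) + 1
  j <- floor(mid2 / res) + 1
  swap <- i > j
  if (any(swap)) { tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp }
  usable <- (i - W >= 1) & (j + W <= n) & ((j - W) - (i + W) >= 1) &
    loops$chrom1 == map$chrom & loops$chrom2 == map$chrom
  n_excl <- sum(!usable)
  if (n_excl > 0)
    message(n_excl, " loop(s) excluded (diagonal/edge proximity or chromosome mismatch)")
  if (!any(usable)) stop("no usable loops for APA")
  i <- i[usable]; j <- j[usable]
  L <- 2 * W + 1
  agg <- matrix(0, L, L)
  for (k in seq_along(i))
    agg <- agg + B[(i[k] - W):(i[k] + W), (j[k] - W):(j[k] + W)]
  agg <- agg / length(i)
  corner_rows <- (L - corner + 1):L
  corner_cols <- 1:corner
  corner_values <- as.numeric(agg[corner_rows, corner_cols])
  cm <- mean(corner_values)
  p2ll <- if (cm > 0) agg[W + 1, W + 1] / cm else NA_real_
  structure(list(agg = agg, p2ll = p2ll, n_loops_used = length(i),
                 n_excluded = n_excl, corner_values = corner_values,
                 window_bins = W, corner = corner),
            class = "apa_result")
}

#' @export
print.apa_result <- function(x, ...) {
  cat(sprintf("APA over %d loops (%d excluded): P2LL = %.3f\n",
              x$n_loops_used, x$n_excluded, x$p2ll))
  invisible(x)
}

#' Classify chromatin loops by network membership and CTCF anchors
#'
#' A loop belongs to the network if at least one anchor overlaps a cisRE
#' linked to a network gene; it is CTCF-mediated if at least one anchor
#' overlaps a CTCF footprint. Genes are assigned to a loop when their span
#' lies within the genomic domain between the outer anchor edges.
#'
#' @param loops Loop data frame (BEDPE columns).
#' @param ctcf_footprints Interval data frame of CTCF footprints.
#' @param cisre_links Data frame with cisRE interval columns
#'   (`chrom,start,end`) and a `gene` column (one row per cisRE-gene link).
#' @param network_genes Character vector of network member genes.
#' @param gene_spans Optional interval data frame with a `gene` column
#'   giving gene body spans, used for domain gene assignment.
#' @return List with `all`, `network`, `ctcf_network`, `nonctcf_network`
#'   loop data frames (each with logical helper columns) and `domain_genes`
#'   (loop index -> genes) when `gene_spans` is supplied.
#' @export
classify_loops <- function(loops, ctcf_footprints, cisre_links,
                           network_genes, gene_spans = NULL) {
  anchor1 <- data.frame(chrom = loops$chrom1, start = loops$start1,
                        end = loops$end1, stringsAsFactors = FALSE)
  anchor2 <- data.frame(chrom = loops$chrom2, start = loops$start2,
                        end = loops$end2, stringsAsFactors = FALSE)
  net_cisres <- cisre_links[cisre_links$gene %in% network_genes, , drop = FALSE]
  hit_any <- function(anchors, targets) {
    if (nrow(targets) == 0 || nrow(anchors) == 0)
      return(rep(FALSE, nrow(anchors)))
    GenomicRanges::countOverlaps(as_granges(anchors), as_granges(targets),
                                 ignore.strand = TRUE) > 0
  }
  in_network <- hit_any(anchor1, net_cisres) | hit_any(anchor2, net_cisres)
  has_ctcf <- hit_any(anchor1, ctcf_footprints) | hit_any(anchor2, ctcf_footprints)
  loops$network <- in_network
  loops$ctcf <- has_ctcf
  out <- list(all = loops,
              network = loops[in_network, , drop = FALSE],
              ctcf_network = loops[in_network & has_ctcf, , drop = FALSE],
              nonctcf_network = loops[in_network & !has_ctcf, , drop = FALSE])
  if (!is.null(gene_spans)) {
    out$domain_genes <- lapply(seq_len(nrow(loops)), function(k) {
      dom_ok <- gene_spans$chrom == loops$chrom1[k] &
        gene_spans$start >= loops$start1[k] &
        gene_spans$end <= loops$end2[k]
      gene_spans$gene[dom_ok]
    })
  }
  out
}

#' Contrast APA corner background distributions between two conditions
#'
#' Standard-normalizes each corner distribution within itself and compares
#' them with a two-sided Student's t-test; the standardized peak (center)
#' value of each APA is reported separately.
#'
#' @param apa_a,apa_b [apa()] results computed on the same loop set.
#' @return List with standardized corner vectors, the t statistic, p-value
#'   and the standardized peak values.
#' @export
corner_contrast <- function(apa_a, apa_b) {
  stopifnot(inherits(apa_a, "apa_result"), inherits(apa_b, "apa_result"))
  za <- apa_a$corner_values; zb <- apa_b$corner_values
  if (stats::sd(za) == 0 || stats::sd(zb) == 0)
    stop("corner distribution has zero variance")
  peak_a <- (apa_a$agg[apa_a$window_bins + 1, apa_a$window_bins + 1] -
               mean(za)) / stats::sd(za)
  peak_b <- (apa_b$agg[apa_b$window_bins + 1, apa_b$window_bins + 1] -
               mean(zb)) / stats::sd(zb)
  sa <- (za - mean(za)) / stats::sd(za)
  sb <- (zb - mean(zb)) / stats::sd(zb)
  tt <- stats::t.test(sa, sb, var.equal = TRUE)
  list(std_a = sa, std_b = sb, t = unname(tt$statistic),
       p = tt$p.value, peak_a = peak_a, peak_b = peak_b)
}

#' @export
plot.apa_result <- function(x, main = sprintf("APA (P2LL = %.2f)", x$p2ll),
                            ...) {
  L <- 2 * x$window_bins + 1
  graphics::image(seq_len(L), seq_len(L), t(x$agg[L:1, ]),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "anchor 2 offset (bins)",
                  ylab = "anchor 1 offset (bins)", axes = FALSE,
                  main = main, ...)
  graphics::axis(1, at = c(1, x$window_bins + 1, L),
                 labels = c(-x$window_bins, 0, x$window_bins))
  graphics::axis(2, at = c(1, x$window_bins + 1, L),
                 labels = c(x$window_bins, 0, -x$window_bins))
  graphics::box()
  invisible(x)
}
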