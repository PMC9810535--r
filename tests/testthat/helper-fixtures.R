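# shared fixture builders for the test suite

toy_genome <- function() genome(c(chr1 = 1e6, chr2 = 5e5))

# uniformly random intervals on a small coordinate range (for brute-force
# per-base oracles)
random_toy_intervals <- function(n, max_pos = 500, max_width = 40,
                                 chroms = c("chr1", "chr2"), seed = 1) {
  set.seed(seed)
  start <- sample.int(max_pos, n, replace = TRUE) - 1
  width <- sample.int(max_width, n, replace = TRUE)
  gintervals(sample(chroms, n, replace = TRUE), start, start + width)
}

# per-base membership oracle for interval-set union
base_union_oracle <- function(x) {
  do.call(rbind, lapply(split(x, x$chrom), function(xc) {
    covered <- rep(FALSE, max(xc$end))
    for (i in seq_len(nrow(xc)))
      covered[(xc$start[i] + 1):xc$end[i]] <- TRUE
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    data.frame(chrom = xc$chrom[1], start = starts[keep], end = ends[keep],
               stringsAsFactors = FALSE)
  }))
}

# brute-force weighted K-S running-sum ES (independent of the package path)
brute_es <- function(metric, gene_set, weight) {
  ord <- order(metric, decreasing = TRUE)
  genes <- names(metric)[ord]
  hit <- genes %in% gene_set
  w <- abs(metric[ord])^weight
  inc <- ifelse(hit, w / sum(w[hit]), -1 / sum(!hit))
  rs <- cumsum(inc)
  rs[which.max(abs(rs))]
}

# small symmetric random contact matrix with positive support
random_contact <- function(n, seed = 1, resolution = 25000) {
  set.seed(seed)
  m <- matrix(runif(n * n, 0.1, 1), n)
  contact_map(m + t(m), resolution)
}

# loops for a 400-bin, 25-kb synthetic chromosome
make_loops <- function(n = 20, seed = 1, strength_a = 1, strength_b = 2,
                       n_bins = 400, res = 25000) {
  set.seed(seed)
  d <- sample(30:55, n, replace = TRUE)
  i <- sample(12:(n_bins - 67), n)
  j <- i + d
  data.frame(chrom1 = "chr1", start1 = (i - 1) * res, end1 = i * res,
             chrom2 = "chr1", start2 = (j - 1) * res, end2 = j * res,
             strength_a = strength_a, strength_b = strength_b,
             stringsAsFactors = FALSE)
}
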