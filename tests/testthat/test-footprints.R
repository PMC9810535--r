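test_that("cleavage profiles: flat input, planted protection, strand handling", {
  flank <- 10; width <- 5; L <- width + 2 * flank
  flat <- matrix(4, 1, L)
  cp <- cleavage_profile(flat, flank = flank)
  expect_equal(cp$profile, rep(1 / L, L))
  expect_equal(sum(cp$profile), 1)

  # planted protection: motif bases carry 20% of flank cleavage
  set.seed(51)
  lam <- rep(10, L); lam[(flank + 1):(flank + width)] <- 2
  cc <- matrix(rpois(40 * L, rep(lam, each = 40)), 40, L)
  cp2 <- cleavage_profile(cc, flank = flank)
  inside <- mean(cp2$profile[(flank + 1):(flank + width)])
  outside <- mean(cp2$profile[-((flank + 1):(flank + width))])
  expect_lt(inside, outside)

  # flipping every site's strand leaves a symmetric aggregate unchanged
  sites <- data.frame(chrom = "chr1", start = 1:40, end = 2:41,
                      strand = "+")
  cp_plus <- cleavage_profile(cc, sites, flank = flank)
  sites$strand <- "-"
  cp_minus <- cleavage_profile(cc[, rev(seq_len(L))], sites, flank = flank)
  expect_equal(cp_plus$profile, cp_minus$profile)

  cc_na <- rbind(cc, NA)
  expect_message(cp3 <- cleavage_profile(cc_na, flank = flank), "truncated")
  expect_equal(cp3$n_sites, 40)
  # site order invariance
  cp4 <- cleavage_profile(cc[sample(40), ], flank = flank)
  expect_equal(cp4$profile, cp2$profile)
})

test_that("two-sided hypergeometric co-occurrence equals enumeration", {
  # N = 10 cisREs; A in 5, B in 4, overlap 4
  cis <- gintervals(rep("chr1", 10), (0:9) * 1000, (0:9) * 1000 + 500)
  mk_fp <- function(which_cis)
    gintervals("chr1", cis$start[which_cis] + 10, cis$start[which_cis] + 20)
  fp <- list(A = mk_fp(1:5), B = mk_fp(2:5))
  co <- cooccurrence(fp, cis)
  expect_equal(co$pairs$k, 4)
  # enumeration oracle: all C(10,4) placements of B against fixed A
  combos <- combn(10, 4)
  mass <- dhyper(0:4, 5, 5, 4)
  m_obs <- dhyper(4, 5, 5, 4)
  p_oracle <- mean(apply(combos, 2, function(b)
    mass[length(intersect(b, 1:5)) + 1] <= m_obs * (1 + 1e-7)))
  expect_equal(co$pairs$p, p_oracle)

  # symmetry
  co_swap <- cooccurrence(list(A = fp$B, B = fp$A), cis)
  expect_equal(co_swap$pairs$p, co$pairs$p)

  # TF present in every cisRE: p = 1 against anything
  fp_all <- list(A = mk_fp(1:10), B = mk_fp(c(1, 3, 7)))
  expect_equal(cooccurrence(fp_all, cis)$pairs$p, 1)

  # planted OR = 4 pair has the smallest p in a simulated landscape
  g <- toy_genome()
  land <- gen_footprint_landscape(
    g, n_cisres = 400,
    cooccur_pairs = data.frame(tf_a = "ETS", tf_b = "CTCF",
                               odds_ratio = 4),
    seed = 52)
  cop <- cooccurrence(land$footprints_by_tf, land$cisres)
  top <- cop$pairs[which.min(cop$pairs$p), ]
  expect_setequal(c(top$tf_a, top$tf_b), c("ETS", "CTCF"))
})

test_that("occupancy enrichment: embedded peaks, degenerate cover, GRanges parity", {
  g <- toy_genome()
  cis <- random_placement(gintervals(rep("chr1", 150), 0, 600), g, seed = 61)
  # peaks deliberately inside cisREs: empirical p at the floor
  emb <- data.frame(chrom = cis$chrom[1:40], start = cis$start[1:40] + 100,
                    end = cis$start[1:40] + 250, strand = ".")
  oc <- occupancy_enrichment(cis, emb, g, n_perm = 200, seed = 62)
  expect_equal(oc$p_emp, 1 / 201)
  expect_gt(oc$z, 3)
  expect_gte(oc$p_emp, 1 / 201)  # floor property

  # peaks covering the whole (single-chromosome) genome: degenerate z
  g1 <- genome(c(chr1 = 1e6))
  cis1 <- random_placement(gintervals(rep("chr1", 50), 0, 600), g1,
                           seed = 66)
  cover <- gintervals("chr1", 0, 1e6)
  expect_warning(occ <- occupancy_enrichment(cis1, cover, g1, n_perm = 20,
                                             seed = 63), "degenerate")
  expect_equal(occ$z, 0)
  expect_equal(occ$observed, nrow(cis1))

  # fast counting path agrees with the GRanges route on random fixtures
  for (s in 1:5) {
    peaks <- random_placement(gintervals(rep("chr1", 30), 0, 800), g,
                              seed = 70 + s)
    fast <- hemenet:::count_overlapping(cis, peaks)
    gr_count <- sum(GenomicRanges::countOverlaps(
      hemenet:::as_granges(cis), hemenet:::as_granges(peaks),
      ignore.strand = TRUE) > 0)
    expect_equal(fast, gr_count)
  }
})

test_that("footprint spacing is the minimal edge-to-edge gap per cisRE", {
  cis <- gintervals(rep("chr1", 3), c(0, 1000, 2000), c(600, 1600, 2600))
  fp <- list(
    ETS = gintervals("chr1", c(100, 1100), c(110, 1110)),
    CTCF = gintervals("chr1", c(150, 1105), c(160, 1115)))
  sp <- footprint_spacing(fp, cis, "ETS", "CTCF")
  expect_equal(sort(sp$distances), c(0, 40))  # overlap -> 0; 150-110 = 40
  expect_equal(sp$mean_distance, 20)
  expect_error(footprint_spacing(fp, cis[3, ], "ETS", "CTCF"), "no cisRE")

  # random landscape vs brute-force all-pairs oracle
  g <- toy_genome()
  land <- gen_footprint_landscape(g, n_cisres = 60, seed = 64)
  sp2 <- footprint_spacing(land$footprints_by_tf, land$cisres, "ETS", "RUNX")
  fa <- land$footprints_by_tf$ETS; fb <- land$footprints_by_tf$RUNX
  brute <- c()
  for (i in seq_len(nrow(land$cisres))) {
    ci <- land$cisres[i, ]
    ina <- which(fa$chrom == ci$chrom & fa$start < ci$end & fa$end > ci$start)
    inb <- which(fb$chrom == ci$chrom & fb$start < ci$end & fb$end > ci$start)
    if (!length(ina) || !length(inb)) next
    d <- Inf
    for (x in ina) for (y in inb)
      d <- min(d, max(0, max(fa$start[x], fb$start[y]) -
                        min(fa$end[x], fb$end[y])))
    brute <- c(brute, d)
  }
  expect_equal(sort(sp2$distances), sort(brute))
})

test_that("signal contrast matches the exact signed-rank distribution", {
  set.seed(55)
  sig <- matrix(rnorm(16), 8, 2, dimnames = list(NULL, c("HSPC", "Ery")))
  sc <- signal_contrast(sig, reference = "HSPC")
  # exact oracle: enumerate all 2^8 sign assignments of the ranked |diffs|
  d <- sig[, "Ery"] - sig[, "HSPC"]
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), 8))
  v_null <- as.matrix(signs) %*% r
  p_exact <- mean(abs(v_null - sum(r) / 2) >= abs(v_obs - sum(r) / 2))
  expect_equal(sc$tests$p, p_exact)

  # identical vectors -> p = 1
  same <- cbind(HSPC = sig[, 1], T_cell = sig[, 1])
  expect_equal(signal_contrast(same, "HSPC")$tests$p, 1)

  # uniform shift is detected at n = 100
  set.seed(65)
  base <- rnorm(100)
  shifted <- cbind(HSPC = base, Mono = base + 0.5)
  expect_lt(signal_contrast(shifted, "HSPC")$tests$p, 1e-10)

  # posterior sorting is descending
  post <- runif(8)
  srt <- signal_contrast(sig, "HSPC", posterior = post)$sorted_signal
  expect_equal(srt[, 1], sig[order(post, decreasing = TRUE), 1])
})
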