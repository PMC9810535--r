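test_that("every generator is a pure function of its config and seed", {
  cfg <- sc_sim_config(n_cells_per_condition = 50, n_genes = 100, seed = 5)
  expect_identical(gen_sc_counts(cfg)$counts, gen_sc_counts(cfg)$counts)

  expect_identical(gen_lineage_profiles(n_cell_types = 6, n_genes = 200,
                                        gradient_set_size = 20, seed = 6),
                   gen_lineage_profiles(n_cell_types = 6, n_genes = 200,
                                        gradient_set_size = 20, seed = 6))

  expect_identical(gen_multiome(n_genes = 40, n_peaks = 100, seed = 7),
                   gen_multiome(n_genes = 40, n_peaks = 100, seed = 7))

  g <- toy_genome()
  expect_identical(gen_footprint_landscape(g, n_cisres = 50, seed = 8),
                   gen_footprint_landscape(g, n_cisres = 50, seed = 8))

  loops <- make_loops(5, seed = 9)
  expect_identical(gen_contact_map(loops = loops, seed = 9)$A$mat,
                   gen_contact_map(loops = loops, seed = 9)$A$mat)

  ccfg <- cohort_sim_config(n_patients = 30, seed = 10)
  expect_identical(gen_cohort(ccfg, network = paste0("n", 1:5),
                              n_genes = 20),
                   gen_cohort(ccfg, network = paste0("n", 1:5),
                              n_genes = 20))
  # generators do not disturb the caller's RNG stream
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(gen_sc_counts(cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("null single-cell data are exchangeable across conditions", {
  cfg <- sc_sim_config(n_cells_per_condition = 300, n_genes = 400,
                       de_fraction = 0, seed = 11)
  sim <- gen_sc_counts(cfg)
  expect_equal(nrow(sim$truth), 0)
  norm <- normalize_log(sim$counts)
  de <- hurdle_de(norm, sim$cell_meta$condition)
  expect_equal(sum(de$adj_p < 1e-20 & abs(de$log2fc) > 0.05), 0)
  # counts are genuinely integer and non-negative
  expect_true(all(sim$counts >= 0))
  expect_true(is.integer(sim$counts[1, 1]) || all(sim$counts == round(sim$counts)))
})

test_that("planted DE genes carry the requested signed effects", {
  cfg <- sc_sim_config(n_cells_per_condition = 500, n_genes = 500,
                       de_fraction = 0.1, de_log2fc = 2, seed = 12)
  sim <- gen_sc_counts(cfg)
  expect_equal(nrow(sim$truth), 50)
  expect_setequal(unique(abs(sim$truth$effect_log2fc)), 2)
  # raw group means move in the planted direction
  a <- colMeans(sim$counts[sim$cell_meta$condition == "A", sim$truth$gene])
  b <- colMeans(sim$counts[sim$cell_meta$condition == "B", sim$truth$gene])
  up <- sim$truth$direction == "up"
  expect_gt(mean(b[up] > a[up]), 0.9)
  expect_gt(mean(b[!up] < a[!up]), 0.9)
})

test_that("lineage profiles plant a monotone stemness gradient", {
  lp <- gen_lineage_profiles(n_cell_types = 8, gradient_set_size = 30,
                             n_genes = 300, noise_sd = 0.01, seed = 13)
  set_means <- colMeans(lp$profiles[lp$truth, ])
  expect_true(all(diff(set_means) < 0))
  expect_equal(lp$hsc_column, colnames(lp$profiles)[1])
})

test_that("multiome generator plants the advertised correlation structure", {
  mo <- gen_multiome(n_genes = 100, n_peaks = 300, linked_fraction = 0.3,
                     link_r = 0.8, seed = 14)
  rs <- vapply(seq_len(nrow(mo$truth)), function(i)
    cor(mo$accessibility[mo$truth$cisre_id[i], ],
        mo$expression[mo$truth$gene[i], ]), numeric(1))
  expect_gt(mean(rs), 0.5)   # 18 populations, target 0.8
  # unlinked peak-gene combinations have near-zero average correlation
  set.seed(15)
  bg <- replicate(200, {
    p <- sample(rownames(mo$accessibility), 1)
    g <- sample(rownames(mo$expression), 1)
    if (paste(p, g) %in% paste(mo$truth$cisre_id, mo$truth$gene)) NA else
      cor(mo$accessibility[p, ], mo$expression[g, ])
  })
  expect_lt(abs(mean(bg, na.rm = TRUE)), 0.1)
  # planted peaks sit within the window of their gene's TSS
  idx <- match(mo$truth$cisre_id, mo$peaks$cisre_id)
  gidx <- match(mo$truth$gene, mo$tss$gene)
  mid <- (mo$peaks$start[idx] + mo$peaks$end[idx]) / 2
  expect_true(all(abs(mid - mo$tss$pos[gidx]) <= 5e5))
  expect_true(all(mo$peaks$chrom[idx] == mo$tss$chrom[gidx]))
})

test_that("footprint landscape hits the requested co-occurrence odds ratio", {
  g <- toy_genome()
  land <- gen_footprint_landscape(
    g, n_cisres = 4000,
    cooccur_pairs = data.frame(tf_a = "ETS", tf_b = "CTCF", odds_ratio = 4),
    seed = 16)
  m <- land$membership
  tab <- table(m[, "ETS"], m[, "CTCF"])
  or_hat <- tab[1, 1] * tab[2, 2] / (tab[1, 2] * tab[2, 1])
  expect_gt(or_hat, 2.5)
  expect_lt(or_hat, 6.5)
  # independent pairs stay near OR = 1
  tab0 <- table(m[, "RUNX"], m[, "JUN"])
  or0 <- tab0[1, 1] * tab0[2, 2] / (tab0[1, 2] * tab0[2, 1])
  expect_gt(or0, 0.6); expect_lt(or0, 1.6)
  # cut counts show depleted cleavage inside the motif
  cc <- land$cut_counts_by_tf$ETS
  prof <- cleavage_profile(cc, flank = 250)
  inside <- (250 + 1):(250 + prof$motif_width)
  expect_lt(mean(prof$profile[inside]),
            0.5 * mean(prof$profile[-inside]))
})

test_that("contact maps follow decay and reject bad loop geometry", {
  loops <- make_loops(10, seed = 17)
  maps <- gen_contact_map(loops = loops, seed = 18)
  m <- maps$A$mat
  d <- abs(row(m) - col(m))
  m1 <- mean(m[d == 2]); m2 <- mean(m[d == 40])
  expect_gt(m1, m2 * 5)   # decay exponent 1: 20x expected
  near <- data.frame(chrom1 = "chr1", start1 = 0, end1 = 25000,
                     chrom2 = "chr1", start2 = 250000, end2 = 275000,
                     strength_a = 1, strength_b = 1)
  expect_error(gen_contact_map(loops = near, seed = 1), "diagonal")
})

test_that("cohort generator calibrates hazard and censoring", {
  cfg <- cohort_sim_config(n_patients = 2000, enriched_fraction = 0.5,
                           true_hr = 2, censor_rate = 0.25, seed = 19)
  sim <- gen_cohort(cfg, network = paste0("n", 1:10), n_genes = 50)
  # oracle Cox on the planted labels recovers the hazard ratio
  cx <- cox_model(sim$cohort$time, sim$cohort$event,
                  data.frame(enriched = as.numeric(sim$truth)))
  expect_true(cx$table$ci_low <= 2 & 2 <= cx$table$ci_high)
  # censoring near the requested rate in the baseline group
  cens_base <- 1 - mean(sim$cohort$event[!sim$truth])
  expect_lt(abs(cens_base - 0.25), 0.06)
  # network genes up-shifted in enriched patients only
  net_means <- rowMeans(sim$expression[, paste0("n", 1:10)])
  expect_gt(mean(net_means[sim$truth]) - mean(net_means[!sim$truth]), 1)
  # null hazard: log-rank p roughly uniform (no planted effect)
  ps <- sapply(1:20, function(s) {
    c0 <- cohort_sim_config(n_patients = 150, true_hr = 1, seed = s)
    s0 <- gen_cohort(c0, network = paste0("n", 1:10), n_genes = 50)
    km_logrank(ifelse(s0$truth, "e", "n"), s0$cohort$time,
               s0$cohort$event)$p_logrank
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})
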