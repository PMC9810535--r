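test_that("GSEA enrichment score equals the brute-force running sum", {
  set.seed(91)
  metric <- setNames(rnorm(10), paste0("g", 1:10))
  for (gs in list(paste0("g", c(2, 5, 9)), paste0("g", 1:3),
                  paste0("g", c(1, 10)))) {
    for (wt in c(0, 1)) {
      got <- preranked_gsea(metric, gs, weight = wt, n_perm = 50, seed = 1)
      expect_equal(got$es, brute_es(metric, gs, wt),
                   info = paste(wt, paste(gs, collapse = ",")))
    }
  }
  # top-k set, weight 0: running-sum maximum is 1 - misses before the peak
  top3 <- names(sort(metric, decreasing = TRUE))[1:3]
  got <- preranked_gsea(metric, top3, weight = 0, n_perm = 50, seed = 1)
  expect_equal(got$es, 1)
  expect_error(preranked_gsea(metric, "absent"), "intersect")
})

test_that("unweighted ES is antisymmetric under set complementation", {
  set.seed(92)
  for (i in 1:5) {
    metric <- setNames(rnorm(30), paste0("g", 1:30))
    gs <- sample(names(metric), 8)
    e1 <- preranked_gsea(metric, gs, weight = 0, n_perm = 20, seed = 1)$es
    e2 <- preranked_gsea(metric, setdiff(names(metric), gs), weight = 0,
                         n_perm = 20, seed = 1)$es
    expect_equal(e1, -e2)
  }
})

test_that("uniformly interleaved sets are neutral; fgsea agrees on ES", {
  metric <- setNames(seq(3, -3, length.out = 20), paste0("g", 1:20))
  inter <- paste0("g", seq(2, 20, by = 2))
  r <- preranked_gsea(metric, inter, weight = 0, n_perm = 200, seed = 3)
  expect_lt(abs(r$es), 0.15)
  expect_equal(r$call, "neutral")
  # independent implementation cross-check (weight 1)
  set.seed(93)
  metric2 <- setNames(rnorm(200), paste0("g", 1:200))
  gs <- paste0("g", sample(200, 25))
  ours <- preranked_gsea(metric2, gs, weight = 1, n_perm = 100, seed = 4)
  ref <- suppressWarnings(
    fgsea::fgsea(list(s = gs), metric2, nPermSimple = 500,
                 gseaParam = 1, scoreType = "std"))
  expect_equal(ours$es, ref$ES, tolerance = 1e-8)
})

test_that("per-sample rank metric centers on the cohort and corrects study", {
  # hand 3-gene case, >= 10 samples
  expr <- matrix(rep(c(1, 2, 3), each = 12), 12, 3,
                 dimnames = list(paste0("s", 1:12), paste0("g", 1:3)))
  expr[1, ] <- expr[1, ] + c(1, -1, 0)
  m <- sample_rank_metric(expr, sample_id = "s1")
  # metric = own value minus cohort mean
  expect_equal(unname(m), unname(expr[1, ] - colMeans(expr)))
  # a sample sitting at the cohort mean has an all-zero metric
  set.seed(98)
  expr2 <- matrix(rnorm(12 * 3), 12, 3,
                  dimnames = list(paste0("s", 1:12), paste0("g", 1:3)))
  mm <- sample_rank_metric(expr2)
  expr2b <- rbind(expr2, s13 = colMeans(rbind(expr2, colMeans(expr2))))
  # s13 equals the mean of the 13-sample cohort by construction
  m13 <- sample_rank_metric(expr2b, sample_id = "s13")
  expect_equal(unname(m13), c(0, 0, 0), tolerance = 1e-12)
  # study correction removes a pure study offset
  study <- rep(c("TCGA", "BEAT"), each = 6)
  expr3 <- expr2
  expr3[study == "BEAT", ] <- expr3[study == "BEAT", ] + 5
  m_corr <- sample_rank_metric(expr3, study = study)
  m_plain <- sample_rank_metric(expr2, study = study)
  expect_equal(m_corr, m_plain, tolerance = 1e-9)
  expect_error(sample_rank_metric(expr[1:5, ]), "at least 10")
})

test_that("Youden threshold equals exhaustive grid search", {
  # perfectly separating score
  sc <- c(1, 2, 3, 10, 11, 12)
  out <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  y <- youden_threshold(sc, out)
  expect_equal(y$j, 1)
  expect_equal(y$threshold, 6.5)

  # 6-point hand example with imperfect separation
  sc2 <- c(0.1, 0.3, 0.35, 0.5, 0.7, 0.9)
  out2 <- c(FALSE, TRUE, FALSE, TRUE, TRUE, FALSE)
  y2 <- youden_threshold(sc2, out2)
  grid_oracle <- function(score, outcome) {
    u <- sort(unique(score))
    cand <- (u[-1] + u[-length(u)]) / 2
    j <- sapply(cand, function(th) {
      mean(score[outcome] >= th) + mean(score[!outcome] < th) - 1
    })
    list(threshold = cand[which.max(j)], j = max(j))
  }
  o2 <- grid_oracle(sc2, out2)
  expect_equal(y2$threshold, o2$threshold)
  expect_equal(y2$j, o2$j)

  # random scores: always identical to the grid oracle
  set.seed(94)
  for (i in 1:10) {
    score <- rnorm(40)
    outcome <- runif(40) < 0.4
    if (length(unique(outcome)) < 2) next
    got <- youden_threshold(score, outcome)
    want <- grid_oracle(score, outcome)
    expect_equal(got$threshold, want$threshold)
    expect_equal(got$j, want$j)
  }
  expect_error(youden_threshold(1:5, rep(TRUE, 5)), "both outcome")
})

test_that("log-rank test matches a hand-computed table on 8 subjects", {
  # classic two-group example, no ties within risk sets at event times
  time <- c(2, 4, 5, 7, 3, 6, 8, 9)
  event <- c(1, 1, 0, 1, 1, 1, 1, 0)
  grp <- rep(c("A", "B"), each = 4)
  km <- km_logrank(grp, time, event)
  # oracle: log-rank O-E and hypergeometric variance at each event time
  ev_times <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    n1 <- sum(at_risk & grp == "A"); n <- sum(at_risk)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & grp == "A")
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq_oracle <- (O - E)^2 / V
  expect_equal(km$chisq, chisq_oracle, tolerance = 1e-8)
  expect_equal(km$p_logrank, pchisq(chisq_oracle, 1, lower.tail = FALSE),
               tolerance = 1e-8)
  # identical groups: chi-square about 0
  km0 <- km_logrank(rep(c("A", "B"), each = 4), rep(time[1:4], 2),
                    rep(event[1:4], 2))
  expect_lt(km0$chisq, 1e-10)
  # truncation censors at the cutoff
  kmt <- km_logrank(grp, time, event, truncate_days = 5)
  expect_equal(max(kmt$fit$time), 5)
})

test_that("trend test appears for >2 ordered groups and detects gradients", {
  set.seed(95)
  n <- 150
  g <- factor(sample(c("favorable", "intermediate", "adverse"), n, TRUE),
              levels = c("favorable", "intermediate", "adverse"),
              ordered = TRUE)
  lambda <- 0.001 * 3^(as.numeric(g) - 1)
  time <- rexp(n, lambda)
  km <- km_logrank(g, time, rep(1, n))
  expect_true(!is.null(km$p_trend))
  expect_lt(km$p_trend, 0.001)
})

test_that("Cox fit matches the closed-form partial-likelihood root (no ties)", {
  time <- c(1, 3, 5, 7, 9, 11)
  event <- c(1, 1, 1, 1, 1, 0)
  x <- c(1, 0, 1, 0, 1, 0)
  cx <- cox_model(time, event, data.frame(x = x))
  # oracle: solve the score equation of the exact partial likelihood
  score <- function(b) {
    s <- 0
    for (i in which(event == 1)) {
      rs <- which(time >= time[i])
      s <- s + x[i] - sum(x[rs] * exp(b * x[rs])) / sum(exp(b * x[rs]))
    }
    s
  }
  root <- uniroot(score, c(-5, 5), tol = 1e-10)$root
  expect_equal(cx$table$coef, root, tolerance = 1e-6)
  expect_equal(cx$table$hr, exp(root), tolerance = 1e-6)
  expect_true(cx$table$ci_low <= cx$table$hr &
                cx$table$hr <= cx$table$ci_high)
  expect_error(cox_model(time, event, data.frame(k = rep(1, 6))),
               "constant")
})

test_that("Cox CIs have near-nominal coverage on self-simulated data", {
  set.seed(96)
  n <- 400; reps <- 120
  cover <- logical(reps)
  for (r in seq_len(reps)) {
    x <- rbinom(n, 1, 0.4)
    t_ev <- rexp(n, 0.001 * exp(log(2) * x))
    t_c <- rexp(n, 0.0004)
    cx <- cox_model(pmin(t_ev, t_c), as.numeric(t_ev <= t_c),
                    data.frame(x = x))
    cover[r] <- cx$table$ci_low <= 2 & 2 <= cx$table$ci_high
  }
  expect_gte(mean(cover), 0.89)
  expect_lte(mean(cover), 0.99)
})

test_that("marginal hazard curve: null effect flat at 1, bands sane", {
  set.seed(97)
  n <- 300
  df <- data.frame(nes = rnorm(n), age = rnorm(n, 55, 10),
                   sex = rbinom(n, 1, 0.5))
  t_ev <- rexp(n, 0.001)          # no covariate effect
  cx <- cox_model(t_ev, rep(1, n), df)
  mc <- marginal_hazard_curve(cx, "nes", ages = 55)
  # with a null coefficient the curve stays near 1 everywhere
  expect_lt(max(abs(log(mc$hr))), 0.5)
  expect_true(all(mc$ci_low <= mc$hr & mc$hr <= mc$ci_high))
  # planted log-linear effect is recovered monotone
  t_ev2 <- rexp(n, 0.001 * exp(0.8 * df$nes))
  cx2 <- cox_model(t_ev2, rep(1, n), df)
  mc2 <- marginal_hazard_curve(cx2, "nes", ages = 55)
  expect_true(all(diff(mc2$hr) > 0))
  expect_warning(marginal_hazard_curve(cx2, "nes", grid = c(-100, 100)),
                 "outside")
})

test_that("CCLE stratification splits at the cutoff and subtracts means", {
  expr <- c(l1 = 0.2, l2 = 0.9, l3 = 1.0, l4 = 2.5)
  ceres <- matrix(c(-0.1, -0.2, -0.9, -1.1,
                    0.5, 0.4, 0.6, 0.5), 4, 2,
                  dimnames = list(names(expr), c("MECOM", "CTRL")))
  st <- ccle_stratify_essentiality(expr, ceres, cutoff = 1)
  expect_equal(unname(st$groups), c("low", "low", "high", "high"))
  expect_equal(st$differential[["MECOM"]],
               mean(c(-0.9, -1.1)) - mean(c(-0.1, -0.2)))
  expect_equal(st$differential[["CTRL"]],
               mean(c(0.6, 0.5)) - mean(c(0.5, 0.4)))
  expect_error(ccle_stratify_essentiality(c(l1 = 0.1, l2 = 0.2),
                                          ceres[1:2, , drop = FALSE]),
               "empty")
})
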