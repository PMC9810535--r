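# running-sum enrichment score for hit positions in a ranked list.
# absw: |metric|^weight of the ranked genes (descending metric order).
# pos: sorted hit positions. Returns the signed extremum of the
# classical weighted Kolmogorov-Smirnov running sum.
es_from_positions <- function(absw, pos, N) {
  k <- length(pos)
  w <- absw[pos]
  tw <- sum(w)
  if (tw == 0) w <- rep(1 / k, k) else w <- w / tw
  Phit <- cumsum(w)
  Pmiss_at <- (pos - seq_len(k)) / (N - k)      # misses before each hit
  dev_top <- Phit - Pmiss_at                    # just after each hit
  dev_bottom <- c(0, Phit[-k]) - Pmiss_at       # just before each hit
  hi <- max(dev_top)
  lo <- min(dev_bottom)
  if (hi >= -lo) hi else lo
}

#' Preranked gene-set enrichment (GSEA)
#'
#' Classical weighted Kolmogorov-Smirnov running-sum enrichment: genes are
#' ordered by decreasing metric; hits increment the running sum in
#' proportion to `|metric|^weight`, misses decrement uniformly; the
#' enrichment score (ES) is the signed extremum. The null is built by
#' permuting the gene-set labels (random same-size sets), the normalized
#' enrichment score (NES) is ES divided by the mean |null ES| of matching
#' sign, and the one-sided permutation p is computed within sign, as in
#' standard GSEA. The categorical call is `enriched` (NES > 0,
#' p < `call_p`), `depleted` (NES < 0, p < `call_p`) or `neutral`.
#'
#' @param ranked Named numeric vector: per-gene ranking metric.
#' @param gene_set Character vector of genes.
#' @param weight Hit-weight exponent (0 = unweighted K-S, 1 = classic).
#' @param n_perm Number of label permutations.
#' @param seed Integer seed.
#' @param call_p p-value threshold for the categorical call.
#' @return List of class `"enrichment_result"`: `es`, `nes`, `p_perm`,
#'   `call`, `n_hits`.
#' @export
preranked_gsea <- function(ranked, gene_set, weight = 1, n_perm = 1000,
                           seed = NULL, call_p = 0.05) {
  stopifnot(!is.null(names(ranked)))
  ord <- order(ranked, decreasing = TRUE)
  genes <- names(ranked)[ord]
  hits <- which(genes %in% gene_set)
  k <- length(hits)
  if (k < 1) stop("gene_set does not intersect the ranked list")
  N <- length(ranked)
  if (k >= N) stop("gene_set covers the whole ranked list")
  absw <- abs(ranked[ord])^weight
  es <- es_from_positions(absw, hits, N)
  null_es <- with_seed(seed, vapply(seq_len(n_perm), function(p)
    es_from_positions(absw, sort.int(sample.int(N, k)), N), numeric(1)))
  same <- if (es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
  nes <- if (length(same)) es / mean(abs(same)) else NA_real_
  p_perm <- if (length(same))
    (1 + sum(abs(same) >= abs(es))) / (1 + length(same)) else 1
  call <- if (is.na(nes) || p_perm >= call_p) "neutral"
          else if (nes > 0) "enriched" else "depleted"
  structure(list(es = es, nes = nes, p_perm = p_perm, call = call,
                 n_hits = k), class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("ES %.3f, NES %.3f, p %.4g -> %s (%d hits)\n",
              x$es, x$nes, x$p_perm, x$call, x$n_hits))
  invisible(x)
}

#' Per-sample ranking metric against the cohort average
#'
#' The metric for gene g in a sample is its expression minus the cohort
#' mean (log2 scale) — a per-sample log fold change versus the cohort
#' average. When `study` labels are given, per-study gene means are
#' aligned to the overall mean first, so merged multi-study cohorts are
#' comparable.
#'
#' @param expr Samples x genes numeric matrix (log2 scale).
#' @param sample_id Optional single sample (row name); if `NULL`, the
#'   full samples x genes metric matrix is returned.
#' @param study Optional per-sample study labels.
#' @return Named metric vector for one sample, or a matrix for all.
#' @export
sample_rank_metric <- function(expr, sample_id = NULL, study = NULL) {
  stopifnot(is.matrix(expr))
  if (nrow(expr) < 10) stop("need at least 10 samples in the cohort")
  if (!is.null(study)) {
    stopifnot(length(study) == nrow(expr))
    overall <- colMeans(expr)
    for (s in unique(study)) {
      rows <- study == s
      expr[rows, ] <- sweep(expr[rows, , drop = FALSE], 2,
                            colMeans(expr[rows, , drop = FALSE]) - overall)
    }
  }
  metric <- sweep(expr, 2, colMeans(expr))
  if (is.null(sample_id)) return(metric)
  if (!sample_id %in% rownames(metric)) stop("unknown sample_id")
  metric[sample_id, ]
}

#' Optimal dichotomizing threshold by Youden's J
#'
#' Scans the midpoints of sorted unique scores, calling `score >=
#' threshold` positive, and returns the threshold maximizing
#' J = sensitivity + specificity - 1. Ties break toward the lower
#' threshold.
#'
#' @param score Numeric per-sample score.
#' @param outcome Logical/0-1 per-sample outcome.
#' @return List: `threshold`, `j`, `sensitivity`, `specificity`.
#' @export
youden_threshold <- function(score, outcome) {
  outcome <- as.logical(outcome)
  stopifnot(length(score) == length(outcome), !anyNA(score), !anyNA(outcome))
  if (length(unique(outcome)) < 2)
    stop("both outcome classes must be present")
  u <- sort(unique(score))
  if (length(u) < 2) stop("score is constant")
  cand <- (u[-1] + u[-length(u)]) / 2
  npos <- sum(outcome); nneg <- sum(!outcome)
  stats_at <- vapply(cand, function(th) {
    pred <- score >= th
    sens <- sum(pred & outcome) / npos
    spec <- sum(!pred & !outcome) / nneg
    c(sens + spec - 1, sens, spec)
  }, numeric(3))
  best <- which.max(stats_at[1, ])  # which.max takes the first (lowest) tie
  list(threshold = cand[best], j = stats_at[1, best],
       sensitivity = stats_at[2, best], specificity = stats_at[3, best])
}

#' Kaplan-Meier curves with log-rank (and trend) testing
#'
#' Product-limit survival curves per group with a Mantel-Cox log-rank
#' test; when more than two ordered groups are supplied, a test for trend
#' (score test with scores 1..k) is added. Optional administrative
#' truncation censors all follow-up at `truncate_days`.
#'
#' @param groups Per-sample group labels (factor order = trend order).
#' @param time Follow-up time in days.
#' @param event Event indicator (1 = death).
#' @param truncate_days Optional truncation day.
#' @return List: `fit` (a [survival::survfit] object), `p_logrank`,
#'   `chisq`, `p_trend` (when > 2 groups), `n_per_group`.
#' @export
km_logrank <- function(groups, time, event, truncate_days = NULL) {
  groups <- as.factor(groups)
  if (!is.null(truncate_days)) {
    event <- ifelse(time > truncate_days, 0, event)
    time <- pmin(time, truncate_days)
  }
  if (any(table(groups) == 0) || nlevels(droplevels(groups)) < 2)
    stop("need at least 2 non-empty groups")
  df <- data.frame(time = time, event = event, group = groups)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  p_logrank <- stats::pchisq(sd_$chisq, df = length(sd_$n) - 1,
                             lower.tail = FALSE)
  out <- list(fit = fit, chisq = unname(sd_$chisq), p_logrank = p_logrank,
              n_per_group = table(groups))
  if (nlevels(groups) > 2) {
    cx <- survival::coxph(survival::Surv(time, event) ~ as.numeric(group),
                          data = df)
    out$p_trend <- summary(cx)$sctest["pvalue"]
  }
  out
}

#' Cox proportional-hazards model with Efron tie handling
#'
#' Thin wrapper over [survival::coxph()] that validates the design,
#' reports per-covariate hazard ratios with Wald 95% confidence intervals
#' and p-values, and errors on non-convergence.
#'
#' @param time Follow-up time.
#' @param event Event indicator.
#' @param covariates Data frame of covariates (e.g. exposure, age, sex,
#'   study).
#' @param truncate_days Optional administrative truncation.
#' @return List of class `"cox_fit"`: `fit` (coxph) and `table`
#'   (data frame `term`, `coef`, `hr`, `ci_low`, `ci_high`, `p`).
#' @export
cox_model <- function(time, event, covariates, truncate_days = NULL) {
  stopifnot(is.data.frame(covariates), nrow(covariates) == length(time))
  if (!is.null(truncate_days)) {
    event <- ifelse(time > truncate_days, 0, event)
    time <- pmin(time, truncate_days)
  }
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    if (length(unique(v[!is.na(v)])) < 2)
      stop("constant covariate: ", nm)
  }
  if (sum(event) < ncol(covariates))
    stop("fewer events than covariates")
  df <- cbind(data.frame(.time = time, .event = event), covariates)
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(names(covariates), collapse = " + ")))
  fit <- tryCatch(
    survival::coxph(fml, data = df, ties = "efron"),
    warning = function(w) {
      if (grepl("converge|infinite|Loglik", conditionMessage(w)))
        stop("Cox model did not converge cleanly: ", conditionMessage(w))
      suppressWarnings(survival::coxph(fml, data = df, ties = "efron"))
    })
  sm <- summary(fit)
  tab <- data.frame(term = rownames(sm$coefficients),
                    coef = sm$coefficients[, "coef"],
                    hr = sm$coefficients[, "exp(coef)"],
                    ci_low = sm$conf.int[, "lower .95"],
                    ci_high = sm$conf.int[, "upper .95"],
                    p = sm$coefficients[, "Pr(>|z|)"],
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(fit = fit, table = tab, data = df), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox proportional hazards fit (Efron ties)\n")
  print(x$table, digits = 3)
  invisible(x)
}

#' Marginal hazard-ratio curve over an exposure grid, by age
#'
#' For a fitted Cox model containing a continuous exposure (optionally
#' with an exposure-by-age interaction), computes the relative hazard
#' along an exposure grid versus a reference exposure, at given ages, with
#' a delta-method 95% band.
#'
#' @param cox A [cox_model()] result whose design contains `exposure`
#'   (and possibly `exposure:age_var`).
#' @param exposure Name of the exposure term.
#' @param age_var Name of the age term (used only when an interaction is
#'   present).
#' @param grid Exposure grid; defaults to a 25-point span of the observed
#'   exposure.
#' @param ages Ages at which to evaluate the curve (single value when the
#'   model has no interaction).
#' @param ref Reference exposure (default: observed mean).
#' @param interaction Optional name of a precomputed exposure-by-age
#'   product column in the design, if one was supplied to [cox_model()].
#' @return Data frame: `age`, `exposure`, `hr`, `ci_low`, `ci_high`.
#' @export
marginal_hazard_curve <- function(cox, exposure, age_var = "age",
                                  grid = NULL, ages = NULL, ref = NULL,
                                  interaction = NULL) {
  stopifnot(inherits(cox, "cox_fit"))
  fit <- cox$fit
  beta <- stats::coef(fit)
  V <- stats::vcov(fit)
  if (!exposure %in% names(beta)) stop("exposure term not in model: ", exposure)
  obs <- cox$data[[exposure]]
  if (is.null(grid)) grid <- seq(min(obs), max(obs), length.out = 25)
  if (any(grid < min(obs) | grid > max(obs)))
    warning("exposure grid extends outside the observed range")
  if (is.null(ref)) ref <- mean(obs)
  int_term <- interaction %||%
    intersect(c(paste0(exposure, ":", age_var),
                paste0(age_var, ":", exposure)), names(beta))
  if (is.null(ages)) ages <- if (length(int_term)) {
    a <- cox$data[[age_var]]
    stats::quantile(a, c(0.25, 0.5, 0.75), names = FALSE)
  } else NA_real_
  out <- do.call(rbind, lapply(ages, function(a) {
    slope <- beta[[exposure]] +
      if (length(int_term)) a * beta[[int_term]] else 0
    if (length(int_term)) {
      vs <- V[exposure, exposure] + a^2 * V[int_term, int_term] +
        2 * a * V[exposure, int_term]
    } else vs <- V[exposure, exposure]
    d <- grid - ref
    se <- abs(d) * sqrt(vs)
    eta <- d * slope
    data.frame(age = a, exposure = grid, hr = exp(eta),
               ci_low = exp(eta - 1.96 * se),
               ci_high = exp(eta + 1.96 * se))
  }))
  rownames(out) <- NULL
  out
}

#' Stratify cell lines by expression and contrast CRISPR essentiality
#'
#' Splits lines into low/high groups at the `log2(RPKM + 1)` cutoff
#' (boundary value assigned to the high group) and computes, per gene,
#' the differential essentiality `mean CERES(high) - mean CERES(low)`;
#' negative values mean stronger essentiality in the high-expression
#' group.
#'
#' @param expr Named per-line expression, `log2(RPKM + 1)` scale.
#' @param ceres Lines x genes CERES gene-effect matrix.
#' @param cutoff Expression cutoff.
#' @return List: `groups` (named character), `differential` (named
#'   per-gene numeric), `n_high`, `n_low`.
#' @export
ccle_stratify_essentiality <- function(expr, ceres, cutoff = 1) {
  stopifnot(!is.null(names(expr)), is.matrix(ceres))
  shared <- intersect(names(expr), rownames(ceres))
  if (!length(shared)) stop("no shared cell lines")
  expr <- expr[shared]; ceres <- ceres[shared, , drop = FALSE]
  high <- expr >= cutoff
  if (!any(high) || all(high)) stop("one of the expression groups is empty")
  diff <- colMeans(ceres[high, , drop = FALSE]) -
    colMeans(ceres[!high, , drop = FALSE])
  list(groups = ifelse(high, "high", "low"),
       differential = diff, n_high = sum(high), n_low = sum(!high))
}
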