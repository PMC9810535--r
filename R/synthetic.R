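#' Configuration for the two-condition single-cell count simulator
#'
#' Defaults emulate a CRISPR perturbation experiment in long-term HSCs:
#' two conditions of a few thousand cells, ~2,000 well-expressed genes,
#' a small planted fraction of differentially expressed genes at modest
#' fold changes, negative-binomial noise and mean-dependent extra
#' dropout.
#'
#' @param n_cells_per_condition Cells per condition.
#' @param n_genes Number of genes.
#' @param de_fraction Fraction of genes planted as DE (half up, half
#'   down in condition B).
#' @param de_log2fc Planted absolute log2 fold change on the raw mean.
#' @param nb_dispersion Negative-binomial dispersion (1/size).
#' @param dropout_logit_slope Slope of the mean-dependent extra dropout
#'   (larger = stronger zero inflation of low-mean genes).
#' @param seed Integer seed.
#' @return List of class `"sc_sim_config"`.
#' @export
sc_sim_config <- function(n_cells_per_condition = 2000, n_genes = 2000,
                          de_fraction = 0.05, de_log2fc = 1,
                          nb_dispersion = 0.5, dropout_logit_slope = 1,
                          seed = 1) {
  stopifnot(n_genes > 0, de_fraction >= 0, de_fraction <= 1,
            nb_dispersion > 0)
  structure(list(n_cells_per_condition = n_cells_per_condition,
                 n_genes = n_genes, de_fraction = de_fraction,
                 de_log2fc = de_log2fc, nb_dispersion = nb_dispersion,
                 dropout_logit_slope = dropout_logit_slope, seed = seed),
            class = "sc_sim_config")
}

#' Simulate two-condition single-cell RNA counts with planted DE genes
#'
#' Counts are negative binomial around per-gene base means (log-normal
#' across genes, centered near two counts per cell — the well-detected
#' gene regime that perturbation DE analysis targets) scaled
#' by per-cell size factors; planted genes have their mean shifted by
#' `de_log2fc` (sign alternating) in condition B. Extra dropout with
#' probability increasing for low-mean genes adds the zero inflation the
#' hurdle test assumes. The planted truth is returned alongside and is
#' never consumed by pipeline stages.
#'
#' @param cfg A [sc_sim_config()].
#' @return List: `counts` (cells x genes), `cell_meta` (`cell`,
#'   `condition` with levels A = control, B = perturbed), `gene_ids`,
#'   `truth` (`gene`, `effect_log2fc`, `direction`).
#' @export
gen_sc_counts <- function(cfg) {
  stopifnot(inherits(cfg, "sc_sim_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_cells_per_condition; G <- cfg$n_genes
    genes <- sprintf("gene_%04d", seq_len(G))
    cells <- sprintf("cell_%05d", seq_len(2 * n))
    condition <- factor(rep(c("A", "B"), each = n))
    base_mu <- stats::rlnorm(G, meanlog = log(2), sdlog = 1)
    n_de <- round(cfg$de_fraction * G)
    de_idx <- if (n_de > 0) sample.int(G, n_de) else integer()
    effect <- numeric(G)
    if (n_de > 0)
      effect[de_idx] <- rep_len(c(1, -1), n_de) * cfg$de_log2fc
    sf <- stats::rlnorm(2 * n, meanlog = 0, sdlog = 0.3)
    size <- 1 / cfg$nb_dispersion
    mu_a <- base_mu
    mu_b <- base_mu * 2^effect
    counts <- matrix(0L, 2 * n, G, dimnames = list(cells, genes))
    for (j in seq_len(G)) {
      mu_cell <- c(rep(mu_a[j], n), rep(mu_b[j], n)) * sf
      x <- stats::rnbinom(2 * n, mu = mu_cell, size = size)
      # mean-dependent extra dropout (zero inflation)
      p_drop <- stats::plogis(-3 - cfg$dropout_logit_slope * log(mu_cell))
      x[stats::runif(2 * n) < p_drop] <- 0L
      counts[, j] <- x
    }
    truth <- data.frame(gene = genes[de_idx],
                        effect_log2fc = effect[de_idx],
                        direction = ifelse(effect[de_idx] > 0, "up", "down"),
                        stringsAsFactors = FALSE)
    list(counts = counts,
         cell_meta = data.frame(cell = cells, condition = condition,
                                stringsAsFactors = FALSE),
         gene_ids = genes, truth = truth)
  })
}

#' Simulate bulk lineage expression profiles with a stemness-graded set
#'
#' Log2-normalized profiles over hematopoietic cell types (column 1 is
#' the designated HSC population). A planted gene set decreases
#' monotonically from the HSC column along the differentiation order.
#'
#' @param n_cell_types Number of cell types (>= 2).
#' @param gradient_set_size Planted set size.
#' @param n_genes Total genes.
#' @param gradient_height Expression drop (log2 units) from HSC to the
#'   most differentiated column for planted genes.
#' @param noise_sd Per-entry Gaussian noise, log2 units.
#' @param seed Integer seed.
#' @return List: `profiles` (genes x cell types), `truth` (planted gene
#'   names), `hsc_column`.
#' @export
gen_lineage_profiles <- function(n_cell_types = 20, gradient_set_size = 100,
                                 n_genes = 2000, gradient_height = 3,
                                 noise_sd = 0.5, seed = 1) {
  stopifnot(n_cell_types >= 2, gradient_set_size < n_genes)
  with_seed(seed, {
    genes <- sprintf("gene_%04d", seq_len(n_genes))
    ct <- c("HSC", sprintf("pop_%02d", seq_len(n_cell_types - 1)))
    base <- stats::rnorm(n_genes, mean = 5, sd = 2)
    profiles <- matrix(stats::rnorm(n_genes * n_cell_types, sd = noise_sd),
                       n_genes, n_cell_types,
                       dimnames = list(genes, ct)) + base
    set_idx <- sample.int(n_genes, gradient_set_size)
    grad <- gradient_height * (seq_len(n_cell_types) - 1) / (n_cell_types - 1)
    profiles[set_idx, ] <- profiles[set_idx, ] +
      matrix(gradient_height - grad, gradient_set_size, n_cell_types,
             byrow = TRUE)
    list(profiles = profiles, truth = genes[set_idx], hsc_column = "HSC")
  })
}

#' Simulate multiomic accessibility/expression with planted peak-gene links
#'
#' Lays genes (TSS) evenly along one synthetic chromosome and places one
#' peak near each gene inside `window_bp`, plus unlinked background
#' peaks. For planted links, peak accessibility and gene expression share
#' a latent cross-population factor giving correlation about `link_r`;
#' all other peaks and genes vary independently.
#'
#' @param n_populations Number of cell populations (>= 5).
#' @param n_genes,n_peaks Feature counts.
#' @param linked_fraction Fraction of genes with a planted linked peak.
#' @param link_r Target cross-population correlation of planted pairs.
#' @param window_bp Linking window.
#' @param seed Integer seed.
#' @return List: `accessibility` (peaks x populations), `expression`
#'   (genes x populations), `tss` (gene, chrom, pos, strand), `peaks`
#'   (interval data frame with `cisre_id`), `truth` (planted
#'   `cisre_id`-`gene` pairs), `genome`.
#' @export
gen_multiome <- function(n_populations = 18, n_genes = 200, n_peaks = 600,
                         linked_fraction = 0.25, link_r = 0.8,
                         window_bp = 500000, seed = 1) {
  stopifnot(n_populations >= 5, link_r >= 0, link_r < 1)
  with_seed(seed, {
    pops <- sprintf("pop_%02d", seq_len(n_populations))
    genes <- sprintf("gene_%04d", seq_len(n_genes))
    spacing <- 2 * window_bp + 100000
    # spread genes over several chromosomes so trans null pairs exist
    n_chrom <- max(2, min(10, n_genes %/% 10))
    chrom_of <- rep(sprintf("chr%d", seq_len(n_chrom)), length.out = n_genes)
    idx_in_chrom <- stats::ave(seq_len(n_genes), chrom_of, FUN = seq_along)
    tss_pos <- spacing * idx_in_chrom
    chrom_len <- spacing * (max(idx_in_chrom) + 1)
    g <- genome(structure(rep(chrom_len, n_chrom),
                          names = sprintf("chr%d", seq_len(n_chrom))))
    tss <- data.frame(gene = genes, chrom = chrom_of, pos = tss_pos,
                      strand = "+", stringsAsFactors = FALSE)
    n_linked <- round(linked_fraction * n_genes)
    linked_genes <- sample.int(n_genes, n_linked)
    # one candidate peak per gene (within the window); remainder background
    cand_start <- tss_pos + round(stats::runif(n_genes, -window_bp * 0.8,
                                               window_bp * 0.8 - 500))
    n_bg <- n_peaks - n_genes
    stopifnot(n_bg >= 0)
    bg_chrom <- sample(names(g), n_bg, replace = TRUE)
    bg_start <- round(stats::runif(n_bg, 0, chrom_len - 500))
    peaks <- data.frame(chrom = c(chrom_of, bg_chrom),
                        start = c(cand_start, bg_start),
                        end = c(cand_start, bg_start) + 500,
                        strand = ".", stringsAsFactors = FALSE)
    peaks$cisre_id <- sprintf("cisre_%05d", seq_len(nrow(peaks)))
    a <- sqrt(link_r)
    expr <- matrix(stats::rnorm(n_genes * n_populations), n_genes,
                   n_populations, dimnames = list(genes, pops))
    acc <- matrix(stats::rnorm(n_peaks * n_populations), n_peaks,
                  n_populations, dimnames = list(peaks$cisre_id, pops))
    for (gi in linked_genes) {
      z <- stats::rnorm(n_populations)
      expr[gi, ] <- a * z + sqrt(1 - a^2) * stats::rnorm(n_populations)
      acc[gi, ] <- a * z + sqrt(1 - a^2) * stats::rnorm(n_populations)
    }
    expr <- expr + 6   # log2-normalized-expression-like location
    acc <- acc + 4
    truth <- data.frame(cisre_id = peaks$cisre_id[linked_genes],
                        gene = genes[linked_genes],
                        stringsAsFactors = FALSE)
    list(accessibility = acc, expression = expr, tss = tss, peaks = peaks,
         truth = truth, genome = g)
  })
}

# joint P(A and B) for given marginals and odds ratio (2x2 table root)
joint_from_or <- function(pa, pb, or) {
  if (or == 1) return(pa * pb)
  f <- function(p11) p11 * (1 - pa - pb + p11) / ((pa - p11) * (pb - p11)) - or
  lo <- max(0, pa + pb - 1) + 1e-9
  hi <- min(pa, pb) - 1e-9
  stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
}

#' Simulate a TF footprint landscape with planted co-occurrence
#'
#' Places cisREs uniformly on the genome and assigns each TF's footprint
#' presence per cisRE; planted TF pairs co-occur at the specified odds
#' ratio (others independently at the base rate). Each present footprint
#' gets an interval inside the cisRE, an occupancy posterior, and a
#' per-base cut-count window with depleted cleavage inside the motif.
#'
#' @param genome A [genome()].
#' @param n_cisres Number of cisREs.
#' @param tf_names Character vector of TF motif families.
#' @param cooccur_pairs Data frame `tf_a`, `tf_b`, `odds_ratio` (> 0).
#' @param base_rate Marginal footprint presence probability per TF.
#' @param motif_width Motif width, bp.
#' @param flank Cut-count flank, bp.
#' @param seed Integer seed.
#' @return List: `cisres`, `footprints_by_tf` (interval data frames with
#'   `posterior`), `cut_counts_by_tf` (sites x window matrices),
#'   `membership` (planted truth).
#' @export
gen_footprint_landscape <- function(genome, n_cisres = 500,
                                    tf_names = c("ETS", "RUNX", "JUN",
                                                 "KLF", "CTCF", "GATA"),
                                    cooccur_pairs = NULL, base_rate = 0.3,
                                    motif_width = 12, flank = 250,
                                    seed = 1) {
  if (!is.null(cooccur_pairs) && any(cooccur_pairs$odds_ratio <= 0))
    stop("odds ratios must be positive")
  with_seed(seed, {
    cisre_w <- 600
    cisres <- random_placement(
      data.frame(chrom = names(genome)[1], start = 0, end = cisre_w,
                 strand = ".")[rep(1, n_cisres), ], genome)
    cisres$cisre_id <- sprintf("cisre_%05d", seq_len(n_cisres))
    membership <- matrix(FALSE, n_cisres, length(tf_names),
                         dimnames = list(cisres$cisre_id, tf_names))
    planted_tfs <- character()
    if (!is.null(cooccur_pairs)) {
      for (i in seq_len(nrow(cooccur_pairs))) {
        ta <- cooccur_pairs$tf_a[i]; tb <- cooccur_pairs$tf_b[i]
        p11 <- joint_from_or(base_rate, base_rate, cooccur_pairs$odds_ratio[i])
        u <- stats::runif(n_cisres)
        both <- u < p11
        only_a <- u >= p11 & u < base_rate
        only_b <- u >= base_rate & u < 2 * base_rate - p11
        membership[, ta] <- both | only_a
        membership[, tb] <- both | only_b
        planted_tfs <- c(planted_tfs, ta, tb)
      }
    }
    for (tf in setdiff(tf_names, planted_tfs))
      membership[, tf] <- stats::runif(n_cisres) < base_rate
    footprints_by_tf <- lapply(tf_names, function(tf) {
      idx <- which(membership[, tf])
      if (!length(idx))
        return(data.frame(chrom = character(), start = numeric(),
                          end = numeric(), strand = character(),
                          posterior = numeric()))
      off <- floor(stats::runif(length(idx), 0, cisre_w - motif_width))
      data.frame(chrom = cisres$chrom[idx],
                 start = cisres$start[idx] + off,
                 end = cisres$start[idx] + off + motif_width,
                 strand = sample(c("+", "-"), length(idx), replace = TRUE),
                 posterior = stats::rbeta(length(idx), 5, 2),
                 stringsAsFactors = FALSE)
    })
    names(footprints_by_tf) <- tf_names
    L <- motif_width + 2 * flank
    lambda_flank <- 2; protect <- 0.2
    cut_counts_by_tf <- lapply(tf_names, function(tf) {
      n_sites <- sum(membership[, tf])
      if (!n_sites) return(matrix(numeric(), 0, L))
      lam <- rep(lambda_flank, L)
      lam[(flank + 1):(flank + motif_width)] <- lambda_flank * protect
      matrix(stats::rpois(n_sites * L, rep(lam, each = n_sites)),
             n_sites, L)
    })
    names(cut_counts_by_tf) <- tf_names
    list(cisres = cisres, footprints_by_tf = footprints_by_tf,
         cut_counts_by_tf = cut_counts_by_tf, membership = membership)
  })
}

#' Simulate two-condition contact maps with planted loops
#'
#' Poisson counts around a distance-decay expectation
#' `scale * d^(-decay_exponent)` with focal multiplicative enrichment at
#' planted loop pixels, scaled per condition by the loop strengths. The
#' two returned maps (A, B) share the decay model and differ only in
#' planted strength.
#'
#' @param chrom_length Chromosome length, bp.
#' @param resolution Bin size, bp.
#' @param loops Data frame `chrom1,start1,end1,chrom2,start2,end2,
#'   strength_a,strength_b`; anchors must be at least
#'   `(window + 2) * resolution` from the diagonal.
#' @param decay_exponent Power-law decay exponent.
#' @param diag_scale Expected count at distance 1 bin.
#' @param window Guard window (bins) used in the diagonal-distance check.
#' @param seed Integer seed.
#' @return List: `A`, `B` ([contact_map()]s), `loops`.
#' @export
gen_contact_map <- function(chrom_length = 1e7, resolution = 25000,
                            loops, decay_exponent = 1, diag_scale = 500,
                            window = 10, seed = 1) {
  n <- chrom_length / resolution
  if (n != round(n)) stop("resolution must divide the chromosome length")
  n <- as.integer(n)
  bi <- floor((loops$start1 + loops$end1) / 2 / resolution) + 1
  bj <- floor((loops$start2 + loops$end2) / 2 / resolution) + 1
  if (any(abs(bj - bi) < 2 * window + 2))
    stop("loop anchor too close to the diagonal for the APA window")
  if (any(bi - window < 1 | bj + window > n))
    stop("loop anchor too close to the chromosome edge")
  with_seed(seed, {
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    expected <- diag_scale * pmax(d, 1)^(-decay_exponent)
    enr <- function(strengths) {
      E <- expected
      for (k in seq_along(strengths)) {
        if (strengths[k] == 0) next
        for (di in -1:1) for (dj in -1:1) {
          kern <- exp(-(di^2 + dj^2) / 2)
          i <- bi[k] + di; j <- bj[k] + dj
          E[i, j] <- E[i, j] * (1 + strengths[k] * kern)
          E[j, i] <- E[i, j]
        }
      }
      E
    }
    sample_map <- function(E) {
      up <- upper.tri(E, diag = TRUE)
      m <- matrix(0, n, n)
      m[up] <- stats::rpois(sum(up), E[up])
      m <- m + t(m) - diag(diag(m))
      contact_map(m, resolution)
    }
    list(A = sample_map(enr(loops$strength_a)),
         B = sample_map(enr(loops$strength_b)),
         loops = loops)
  })
}

#' Configuration for the survival cohort simulator
#'
#' @param n_patients Cohort size.
#' @param enriched_fraction Fraction of patients with the network
#'   coherently up-shifted.
#' @param true_hr Hazard ratio of death for enriched patients.
#' @param censor_rate Approximate fraction censored.
#' @param baseline_hazard Exponential baseline hazard per day.
#' @param seed Integer seed.
#' @return List of class `"cohort_sim_config"`.
#' @export
cohort_sim_config <- function(n_patients = 400, enriched_fraction = 0.4,
                              true_hr = 2, censor_rate = 0.3,
                              baseline_hazard = 0.001, seed = 1) {
  stopifnot(true_hr > 0, censor_rate >= 0, censor_rate < 1,
            baseline_hazard > 0)
  structure(list(n_patients = n_patients,
                 enriched_fraction = enriched_fraction, true_hr = true_hr,
                 censor_rate = censor_rate,
                 baseline_hazard = baseline_hazard, seed = seed),
            class = "cohort_sim_config")
}

#' Simulate an expression + survival cohort with planted network enrichment
#'
#' Expression is Gaussian on the log2 scale with per-study gene offsets;
#' enriched patients have the network genes coherently up-shifted.
#' Survival times are exponential with the hazard multiplied by
#' `true_hr` for enriched patients; censoring is independent exponential
#' calibrated to `censor_rate` in the baseline group.
#'
#' @param cfg A [cohort_sim_config()].
#' @param network Character vector of network genes.
#' @param n_genes Total genes (network genes are the first
#'   `length(network)` columns).
#' @param shift Coherent up-shift of network genes in enriched patients
#'   (log2 units).
#' @param studies Study labels to split samples across.
#' @return List: `cohort` (data frame: sample_id, time, event, age, sex,
#'   study, risk_group, lsc17), `expression` (samples x genes matrix),
#'   `truth` (logical enriched flag per sample).
#' @export
gen_cohort <- function(cfg, network = sprintf("net_%03d", 1:40),
                       n_genes = 1000, shift = 1.5,
                       studies = c("TCGA", "BEAT")) {
  stopifnot(inherits(cfg, "cohort_sim_config"),
            length(network) < n_genes)
  with_seed(cfg$seed, {
    n <- cfg$n_patients
    ids <- sprintf("sample_%04d", seq_len(n))
    genes <- c(network, sprintf("bg_%04d", seq_len(n_genes - length(network))))
    study <- sample(studies, n, replace = TRUE)
    study_offset <- matrix(stats::rnorm(length(studies) * n_genes, sd = 0.3),
                           length(studies), n_genes,
                           dimnames = list(studies, genes))
    expr <- matrix(stats::rnorm(n * n_genes, mean = 7, sd = 1), n, n_genes,
                   dimnames = list(ids, genes)) + study_offset[study, ]
    enriched <- stats::runif(n) < cfg$enriched_fraction
    expr[enriched, network] <- expr[enriched, network] + shift
    lambda <- cfg$baseline_hazard * ifelse(enriched, cfg$true_hr, 1)
    t_event <- stats::rexp(n, lambda)
    if (cfg$censor_rate > 0) {
      lam_c <- cfg$baseline_hazard * cfg$censor_rate / (1 - cfg$censor_rate)
      t_cens <- stats::rexp(n, lam_c)
    } else t_cens <- rep(Inf, n)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
    cohort <- data.frame(sample_id = ids, time = round(time, 1),
                         event = event,
                         age = round(pmin(pmax(stats::rnorm(n, 55, 15), 18), 90)),
                         sex = sample(c("F", "M"), n, replace = TRUE),
                         study = study,
                         risk_group = factor(
                           sample(c("favorable", "intermediate", "adverse"),
                                  n, replace = TRUE),
                           levels = c("favorable", "intermediate", "adverse"),
                           ordered = TRUE),
                         lsc17 = stats::rnorm(n),
                         stringsAsFactors = FALSE)
    list(cohort = cohort, expression = expr, truth = enriched)
  })
}
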