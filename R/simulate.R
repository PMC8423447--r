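#' Simulation configuration for a synthetic diet study
#'
#' Defines the study conditions the generator emulates: 35 group-housed
#' animals (20 Western-fed, 15 Mediterranean-fed), ~12,000 expressed genes
#' with negative-binomial counts, a polygenic (kinship-correlated) random
#' effect on log expression, diet main effects whose magnitudes are on
#' average 1.6-fold larger in the Western direction, technical covariate
#' loadings, diet-dependent pairwise co-expression, and a latent diet-altered
#' behavior (DAB) score that partially mediates -- and is partially mediated
#' by -- diet effects on expression.
#'
#' @param n_animals total number of animals.
#' @param n_western number fed the Western diet (the rest are Mediterranean).
#' @param n_genes number of genes.
#' @param n_true_de number of genes given a non-zero diet effect.
#' @param de_effect_scale_west,de_effect_scale_med mean |log2 fold| of
#'   Western- and Mediterranean-direction effects (exponentially distributed
#'   magnitudes). The default ratio is 1.6.
#' @param polygenic_var fraction of the Gaussian log-expression noise variance
#'   attributable to the polygenic (kinship) effect, in `[0, 1)`.
#' @param resid_log_sd total Gaussian log2-expression noise standard deviation
#'   (polygenic + independent parts).
#' @param n_diffcor_pairs number of gene pairs given diet-dependent
#'   co-expression through a shared latent factor active under one diet only.
#' @param diffcor_r target within-diet Pearson correlation for the active diet
#'   of each differentially co-expressed pair.
#' @param mediation_fraction_forward fraction of true-DE genes whose diet
#'   effect is partially transmitted through the DAB score.
#' @param mediation_fraction_reverse fraction of true-DE genes that feed into
#'   the DAB score (expression-mediates-behavior path).
#' @param n_families number of kin families for the block kinship matrix.
#' @param n_contaminated number of samples given a large CD3 marker boost
#'   (emulating inefficient monocyte purification).
#' @param n_sessions_experimental focal-observation sessions per animal in the
#'   experimental phase (baseline is fixed at 12 sessions x 600 s = 2 h).
#' @param assign_by_group if `TRUE` (default) diet is constant within social
#'   groups of 3-4 animals, mirroring pen-level assignment; otherwise groups
#'   mix diets.
#' @param seed integer seed; a fixed seed makes the study byte-identical.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_animals = 35, n_western = 20, n_genes = 12000,
                       n_true_de = round(0.4 * n_genes),
                       de_effect_scale_west = 0.48, de_effect_scale_med = 0.30,
                       polygenic_var = 0.2, resid_log_sd = 0.35,
                       n_diffcor_pairs = 50, diffcor_r = 0.6,
                       mediation_fraction_forward = 0.25,
                       mediation_fraction_reverse = 0.20,
                       n_families = 12, n_contaminated = 0,
                       n_sessions_experimental = 24,
                       assign_by_group = TRUE, seed = 1) {
  cfg <- list(
    n_animals = assert_count(n_animals, "n_animals"),
    n_western = assert_count(n_western, "n_western"),
    n_genes = assert_count(n_genes, "n_genes"),
    n_true_de = assert_count(n_true_de, "n_true_de", positive = FALSE),
    de_effect_scale_west = as.numeric(de_effect_scale_west),
    de_effect_scale_med = as.numeric(de_effect_scale_med),
    polygenic_var = assert_fraction(polygenic_var, "polygenic_var"),
    resid_log_sd = as.numeric(resid_log_sd),
    n_diffcor_pairs = assert_count(n_diffcor_pairs, "n_diffcor_pairs", positive = FALSE),
    diffcor_r = assert_fraction(diffcor_r, "diffcor_r"),
    mediation_fraction_forward = assert_fraction(mediation_fraction_forward, "mediation_fraction_forward"),
    mediation_fraction_reverse = assert_fraction(mediation_fraction_reverse, "mediation_fraction_reverse"),
    n_families = assert_count(n_families, "n_families"),
    n_contaminated = assert_count(n_contaminated, "n_contaminated", positive = FALSE),
    n_sessions_experimental = assert_count(n_sessions_experimental, "n_sessions_experimental"),
    assign_by_group = isTRUE(assign_by_group),
    seed = assert_count(seed, "seed", positive = FALSE)
  )
  if (cfg$n_western >= cfg$n_animals) abort("n_western must be smaller than n_animals")
  if (cfg$n_true_de > cfg$n_genes) abort("n_true_de cannot exceed n_genes")
  if (cfg$polygenic_var >= 1) abort("polygenic_var must be < 1")
  if (cfg$n_families > cfg$n_animals) abort("n_families cannot exceed n_animals")
  if (2L * cfg$n_diffcor_pairs > max(cfg$n_true_de, 1L) && cfg$n_diffcor_pairs > 0)
    abort("n_diffcor_pairs too large for n_true_de (pairs use distinct true-DE genes)")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a block-family kinship matrix
#'
#' Animals are partitioned into families as evenly as possible (membership
#' shuffled under `seed`); relatedness is 1 on the diagonal, 0.25 between
#' members of the same family (half-sibling level) and 0 otherwise. The
#' resulting matrix is symmetric positive semi-definite by construction.
#'
#' @param n_animals,n_families counts with `n_families <= n_animals`.
#' @param seed integer seed for the family-membership shuffle.
#' @return a [kinship_matrix()].
#' @examples
#' simulate_kinship(4, 2, seed = 1)
#' @export
simulate_kinship <- function(n_animals, n_families, seed = 1) {
  n_animals <- assert_count(n_animals, "n_animals")
  n_families <- assert_count(n_families, "n_families")
  if (n_families > n_animals) abort("n_families cannot exceed n_animals")
  set.seed(seed)
  fam <- sample(rep(seq_len(n_families), length.out = n_animals))
  K <- 0.25 * outer(fam, fam, "==") + 0.75 * diag(n_animals)
  ids <- sprintf("animal%02d", seq_len(n_animals))
  dimnames(K) <- list(ids, ids)
  kinship_matrix(K, animal_ids = ids)
}

# social groups of 3-4 animals within one diet arm
#' @keywords internal
make_groups <- function(n, prefix) {
  sizes <- rep(4L, n %/% 4L)
  r <- n %% 4L
  if (r > 0) {
    if (r == 3L || length(sizes) == 0) sizes <- c(sizes, r)
    else { # spread remainder of 1-2 by shrinking existing groups to 3
      for (i in seq_len(4L - r)) sizes[i] <- sizes[i] - 1L
      sizes <- c(sizes, 3L)
    }
  }
  rep(paste0(prefix, seq_along(sizes)), times = sizes)
}

#' Simulate a complete synthetic diet study
#'
#' Generates counts, kinship, sample metadata, a long-format focal-observation
#' behavior table, gene sets and a full ground-truth record under the noise
#' model: per-gene log2 mean = baseline + beta_diet x diet + covariate
#' loadings + polygenic effect ~ MVN(0, sigma_g^2 K) + independent Gaussian
#' noise, with negative-binomial counts (gene-wise log-normal dispersion).
#' Forward-mediated genes receive part of their diet effect through the latent
#' DAB score; reverse-path genes contribute to the DAB score; differentially
#' co-expressed pairs share a latent factor active under one diet only.
#'
#' @param config a [sim_config()].
#' @return an object of class `synthetic_study`: list with elements `counts`
#'   ([count_matrix()]), `kinship`, `metadata`, `behavior`, `gene_sets`,
#'   `truth`, `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  n <- cfg$n_animals
  G <- cfg$n_genes
  kin <- simulate_kinship(n, cfg$n_families, seed = child_seed(cfg$seed, 1))
  ids <- attr(kin, "animal_ids")
  set.seed(child_seed(cfg$seed, 2))

  ## ---- design: diet and social groups ----
  diet <- c(rep("Western", cfg$n_western), rep("Mediterranean", n - cfg$n_western))
  d01 <- as.numeric(diet == "Western")
  if (cfg$assign_by_group) {
    group <- c(make_groups(cfg$n_western, "W"), make_groups(n - cfg$n_western, "M"))
  } else {
    group <- sample(make_groups(n, "G"))
  }

  ## ---- technical covariates ----
  CD14 <- rnorm(n, 10, 1)
  CD3 <- rnorm(n, 4, 1)
  if (cfg$n_contaminated > 0) {
    contam <- sample(n, cfg$n_contaminated)
    CD3[contam] <- CD3[contam] + 8
  }
  RIN <- rnorm(n, 8, 0.5)
  concentration <- rnorm(n, 50, 10)

  ## ---- gene-level parameters ----
  gene_ids <- c("CD14", "CD3E", sprintf("gene%05d", seq_len(G - 2) + 2L))
  gene_lengths <- round(exp(rnorm(G, log(2500), 0.6))) + 200
  base_log2 <- runif(G, 4, 11)
  nb_size <- exp(rnorm(G, log(20), 0.6)) # NB dispersion: var = mu + mu^2/size

  beta <- numeric(G)
  eligible <- 3:G # marker genes carry covariate signal, never planted effects
  de_idx <- if (cfg$n_true_de > 0) sort(sample(eligible, cfg$n_true_de)) else integer(0)
  # direction split mirrors the roughly balanced Western/Mediterranean genes
  p_west <- 0.456
  is_west <- rbinom(length(de_idx), 1, p_west) == 1
  beta[de_idx[is_west]] <- rexp(sum(is_west), rate = 1 / cfg$de_effect_scale_west)
  beta[de_idx[!is_west]] <- -rexp(sum(!is_west), rate = 1 / cfg$de_effect_scale_med)

  ## ---- covariate loadings on a subset of genes ----
  n_load <- max(1L, round(0.1 * G))
  load_idx <- sample(eligible, min(n_load, length(eligible)))
  cov_load <- matrix(0, G, 4)
  cov_load[load_idx, ] <- matrix(rnorm(length(load_idx) * 4, 0, 0.15), ncol = 4)
  cov_load[1, 1] <- 0.8  # CD14 marker gene tracks CD14 covariate
  cov_load[2, 2] <- 0.8  # CD3E marker gene tracks CD3 covariate
  covmat <- cbind(scale(CD14), scale(CD3), scale(RIN), scale(concentration))
  if (cfg$n_contaminated > 0) covmat[, 2] <- CD3 - mean(CD3) # keep contamination magnitude

  ## ---- differentially co-expressed pair genes (strong effects, reserved) ----
  # chosen before the mediation pools so shared-DAB loadings cannot induce
  # correlation in both diets and mask the planted diet-specific factor
  pg <- matrix(integer(0), 0, 2)
  if (cfg$n_diffcor_pairs > 0) {
    ranked <- de_idx[order(-abs(beta[de_idx]))]
    pool <- head(ranked, max(2L * cfg$n_diffcor_pairs, 20L))
    pg <- matrix(sample(pool, 2L * cfg$n_diffcor_pairs), ncol = 2)
  }

  ## ---- reverse-path genes feed the DAB score ----
  med_pool <- setdiff(de_idx, as.vector(pg))
  n_fwd <- round(cfg$mediation_fraction_forward * length(de_idx))
  n_rev <- round(cfg$mediation_fraction_reverse * length(de_idx))
  fwd_idx <- if (n_fwd > 0) sample(med_pool, min(n_fwd, length(med_pool))) else integer(0)
  rev_pool <- setdiff(med_pool, fwd_idx)
  rev_idx <- if (n_rev > 0 && length(rev_pool) > 0) sample(rev_pool, min(n_rev, length(rev_pool))) else integer(0)

  sg2 <- cfg$polygenic_var * cfg$resid_log_sd^2
  se2 <- (1 - cfg$polygenic_var) * cfg$resid_log_sd^2
  eigK <- eigen(unclass(kin), symmetric = TRUE)
  Khalf <- eigK$vectors %*% (sqrt(pmax(eigK$values, 0)) * t(eigK$vectors))
  U <- if (sg2 > 0) Khalf %*% matrix(rnorm(n * G, 0, sqrt(sg2)), n, G) else matrix(0, n, G)
  E <- matrix(rnorm(n * G, 0, sqrt(se2)), n, G)

  # reverse-path genes feed the DAB score through their diet-independent
  # expression fluctuations; because each gene's expression also carries its
  # diet effect, conditioning DAB on the gene recovers a genuine indirect
  # (gene-mediated) diet component without disturbing the DAB diet separation
  z_rev <- if (length(rev_idx) > 0) {
    as.numeric(scale(rowMeans(U[, rev_idx, drop = FALSE] + E[, rev_idx, drop = FALSE])))
  } else rep(0, n)
  dab_latent <- -1.2 * d01 + 0.5 * z_rev + rnorm(n, 0, 0.5)
  dab_z <- as.numeric(scale(dab_latent))

  ## ---- assemble log2 means ----
  M <- matrix(base_log2, n, G, byrow = TRUE)
  prop_true <- rep(NA_real_, G)
  direct <- beta
  if (length(fwd_idx) > 0) {
    # split the total diet effect into a direct part and a DAB-transmitted part
    prop <- runif(length(fwd_idx), 0.3, 0.7)
    a_path <- coef(lm(dab_latent ~ d01))[2]
    b_path <- prop * beta[fwd_idx] / a_path
    direct[fwd_idx] <- beta[fwd_idx] * (1 - prop)
    M[, fwd_idx] <- M[, fwd_idx] + outer(dab_latent, b_path)
    prop_true[fwd_idx] <- prop
  }
  M <- M + d01 %o% direct
  M <- M + covmat %*% t(cov_load)
  M <- M + U + E

  ## ---- differentially co-expressed pairs ----
  pair_truth <- tibble(gene_i = character(0), gene_j = character(0),
                       active_diet = character(0), r_active_target = numeric(0),
                       r_inactive_target = numeric(0))
  if (cfg$n_diffcor_pairs > 0) {
    # per-pair amplitude calibrated against each gene's total log2 noise
    # (Gaussian biological noise + expected NB counting noise at its depth),
    # so the active diet's correlation lands on the target
    nb_logvar <- (1 / 2^base_log2 + 1 / nb_size) / log(2)^2
    v <- cfg$resid_log_sd^2 + nb_logvar
    active <- rep(c("Western", "Mediterranean"), length.out = cfg$n_diffcor_pairs)
    for (p in seq_len(cfg$n_diffcor_pairs)) {
      f <- rnorm(n)
      on <- as.numeric(diet == active[p])
      w <- sqrt(cfg$diffcor_r / (1 - cfg$diffcor_r) * sqrt(v[pg[p, 1]] * v[pg[p, 2]]))
      M[, pg[p, 1]] <- M[, pg[p, 1]] + w * f * on
      M[, pg[p, 2]] <- M[, pg[p, 2]] + w * f * on
    }
    pair_truth <- tibble(gene_i = gene_ids[pg[, 1]], gene_j = gene_ids[pg[, 2]],
                         active_diet = active,
                         r_active_target = cfg$diffcor_r, r_inactive_target = 0)
  }

  ## ---- negative-binomial counts ----
  mu <- 2^M
  counts <- matrix(rnbinom(n * G, mu = mu, size = rep(nb_size, each = n)), n, G,
                   dimnames = list(ids, gene_ids))
  cm <- count_matrix(counts, gene_lengths = gene_lengths,
                     gene_ids = gene_ids, sample_ids = ids)

  ## ---- behavior ----
  behavior <- simulate_behavior(ids, dab_z, cfg$n_sessions_experimental)

  ## ---- gene sets ----
  gene_sets <- simulate_gene_sets(gene_ids, beta, pair_truth)

  metadata <- tibble(
    animal_id = ids, diet = diet, social_group = group,
    CD14 = CD14, CD3 = CD3, RIN = RIN, concentration = concentration
  )
  truth <- list(
    gene_truth = tibble(
      gene = gene_ids, beta_true = beta,
      direction_true = dplyr::case_when(beta > 0 ~ "Western", beta < 0 ~ "Mediterranean", TRUE ~ "NS"),
      is_de = beta != 0,
      forward_mediated = seq_len(G) %in% fwd_idx,
      reverse_path = seq_len(G) %in% rev_idx,
      proportion_mediated_true = prop_true
    ),
    diffcor_pairs = pair_truth,
    dab = tibble(animal_id = ids, dab_true = dab_latent)
  )
  structure(list(counts = cm, kinship = kin, metadata = metadata,
                 behavior = behavior, gene_sets = gene_sets,
                 truth = truth, config = cfg),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %d animals (%d Western), %d genes, %d true-DE, %d diffcor pairs\n",
              x$config$n_animals, x$config$n_western, x$config$n_genes,
              sum(x$truth$gene_truth$is_de), nrow(x$truth$diffcor_pairs)))
  invisible(x)
}

# ethogram generator: states partition each 600 s session; event counts are
# Poisson. Selected behaviors load on the standardized latent DAB score during
# the experimental phase only; baseline sessions are exchangeable across diets.
#' @keywords internal
simulate_behavior <- function(ids, dab_z, n_sessions_exp, session_seconds = 600) {
  states <- c(body_contact = 0.9, rest = 0.45, alone = -0.9, groom_give = 0.35,
              groom_receive = 0.25, proximity = 0.15, locomotion = 0, feed = 0)
  state_base <- c(body_contact = 0.2, rest = 0.6, alone = 0.4, groom_give = -0.6,
                  groom_receive = -0.7, proximity = -0.1, locomotion = -0.3, feed = -0.2)
  events <- c(contact_aggression = -0.35, noncontact_aggression = -0.35,
              submission = -0.25, self_groom = -0.7, scratch = -0.7,
              approach = 0.35, play = 0.2, displacement = 0, vocalization = 0,
              mount = 0)
  event_base <- c(contact_aggression = -0.7, noncontact_aggression = -0.2,
                  submission = 0, self_groom = 0.4, scratch = 0.7, approach = 0.7,
                  play = -0.4, displacement = -0.7, vocalization = 0.4, mount = -1.2)
  phases <- list(baseline = list(n_sessions = 12L, loaded = FALSE),
                 experimental = list(n_sessions = n_sessions_exp, loaded = TRUE))
  rows <- list()
  for (ph in names(phases)) {
    ns <- phases[[ph]]$n_sessions
    eff <- if (phases[[ph]]$loaded) 1 else 0
    for (a in seq_along(ids)) {
      for (s in seq_len(ns)) {
        sid <- sprintf("%s_%s_s%03d", ids[a], substr(ph, 1, 3), s)
        lw <- state_base + eff * states * dab_z[a] + rnorm(length(states), 0, 0.35)
        secs <- session_seconds * exp(lw) / sum(exp(lw))
        lr <- event_base + eff * events * dab_z[a]
        cnt <- rpois(length(events), exp(lr))
        rows[[length(rows) + 1L]] <- tibble(
          animal_id = ids[a], session_id = sid, phase = ph,
          behavior = c(names(states), names(events)),
          kind = c(rep("state", length(states)), rep("event", length(events))),
          value = unname(c(secs, cnt)), session_seconds = session_seconds
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

# synthetic functional gene sets with known planted structure:
# M1 members are ~2x over-represented among Western-direction genes; the CTRA
# categories are drawn from direction-consistent genes; trait_metabolic is
# enriched, trait_neutral is not; TF is a random annotation covering the
# differential-correlation pool.
#' @keywords internal
simulate_gene_sets <- function(gene_ids, beta, pair_truth) {
  G <- length(gene_ids)
  west <- which(beta > 0)
  med <- which(beta < 0)
  other <- setdiff(seq_len(G), c(west, med))
  fw <- length(west) / G
  pick <- function(pool, k) sample(pool, min(k, length(pool)))
  n_m1 <- min(150L, max(10L, round(G / 30)))
  k_w <- round(min(2 * fw, 0.9) * n_m1)
  m1 <- c(pick(west, k_w), pick(setdiff(seq_len(G), west), n_m1 - k_w))
  m2 <- pick(seq_len(G), max(6L, round(n_m1 * 0.4)))
  n_ctra <- max(6L, round(G / 80))
  ctra_pro <- pick(west, n_ctra)
  ctra_av <- pick(med, n_ctra)
  n_tr <- max(8L, round(G / 50))
  k_tw <- round(min(2 * fw, 0.9) * n_tr)
  trait_met <- c(pick(west, k_tw), pick(setdiff(seq_len(G), west), n_tr - k_tw))
  trait_neu <- pick(seq_len(G), n_tr)
  pair_genes <- match(unique(c(pair_truth$gene_i, pair_truth$gene_j)), gene_ids)
  tf <- unique(c(pick(pair_genes, max(3L, round(length(pair_genes) * 0.2))),
                 pick(seq_len(G), max(5L, round(G * 0.05)))))
  lapply(list(
    M1 = m1, M2 = m2,
    CTRA_proinflammatory = ctra_pro, CTRA_antiviral_antibody = ctra_av,
    trait_metabolic = trait_met, trait_neutral = trait_neu,
    TF = tf
  ), function(i) sort(gene_ids[i]))
}

#' Write a synthetic study to plain-text fixture files
#'
#' @param study a [simulate_study()] result.
#' @param directory output directory (created if absent).
#' @return a tibble manifest (`file`, `bytes`), invisibly visible.
#' @export
write_fixture <- function(study, directory) {
  stopifnot(inherits(study, "synthetic_study"))
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  if (file.access(directory, mode = 2) != 0) abort(paste0("directory not writable: ", directory))
  p <- function(f) file.path(directory, f)
  write_counts_tsv(study$counts, p("counts.tsv"))
  write_counts_mtx(study$counts, p("counts"))
  write_tsv_plain(study$metadata, p("metadata.tsv"))
  write_kinship_tsv(study$kinship, p("kinship.tsv"))
  write_tsv_plain(study$behavior, p("behavior.tsv"))
  write_gmt(study$gene_sets, p("gene_sets.gmt"))
  write_tsv_plain(study$truth$gene_truth, p("truth_genes.tsv"))
  write_tsv_plain(study$truth$diffcor_pairs, p("truth_pairs.tsv"))
  write_tsv_plain(study$truth$dab, p("truth_dab.tsv"))
  yaml::write_yaml(unclass(study$config), p("config.yaml"))
  files <- list.files(directory, full.names = TRUE)
  tibble(file = basename(files), bytes = file.size(files))
}

#' Read a synthetic study back from fixture files
#' @param directory directory written by [write_fixture()].
#' @return a `synthetic_study` object.
#' @export
read_fixture <- function(directory) {
  p <- function(f) file.path(directory, f)
  cfg <- do.call(sim_config, yaml::read_yaml(p("config.yaml")))
  structure(list(
    counts = read_counts_tsv(p("counts.tsv")),
    kinship = read_kinship_tsv(p("kinship.tsv")),
    metadata = read_tsv_plain(p("metadata.tsv")),
    behavior = read_tsv_plain(p("behavior.tsv")),
    gene_sets = read_gmt(p("gene_sets.gmt")),
    truth = list(gene_truth = read_tsv_plain(p("truth_genes.tsv")),
                 diffcor_pairs = read_tsv_plain(p("truth_pairs.tsv")),
                 dab = read_tsv_plain(p("truth_dab.tsv"))),
    config = cfg
  ), class = "synthetic_study")
}
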