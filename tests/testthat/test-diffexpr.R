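test_that("differential expression recovers planted diet effects", {
  study <- tiny_study()
  de <- tiny_de()
  tr <- study$truth$gene_truth
  merged <- dplyr::inner_join(de, tr, by = "gene")
  true_de <- merged[merged$is_de, ]
  expect_gte(cor(true_de$beta_diet, true_de$beta_true), 0.9)

  # direction labels partition the genes and conserve the total
  counts <- table(factor(de$direction, levels = c("Western", "Mediterranean", "NS")))
  expect_equal(sum(counts), nrow(de))
  expect_true(all(de$direction[de$fdr < 0.05 & de$beta_diet > 0] == "Western"))
  expect_true(all(de$direction[de$fdr < 0.05 & de$beta_diet < 0] == "Mediterranean"))
})

test_that("differential expression is calibrated on a null study", {
  rates <- vapply(1:3, function(s) {
    null <- simulate_study(sim_config(n_genes = 300, n_true_de = 0, n_diffcor_pairs = 0,
                                      seed = 500 + s))
    norm <- normalize_logcpm_weights(null$counts)
    resid <- residualize_covariates(norm, null$metadata[, c("CD14", "CD3", "RIN", "concentration")])
    de <- suppressMessages(run_de(resid, null$metadata$diet, null$kinship,
                                  n_perm = 50, seed = s))
    mean(de$fdr < 0.05)
  }, numeric(1))
  expect_lte(mean(rates), 0.01)
})

test_that("sample correlation PCA has orthogonal scores and unit-sum variance", {
  set.seed(40)
  Y <- matrix(rnorm(20 * 100), 20, 100)
  pca <- sample_correlation_pca(Y)
  expect_equal(sum(pca$variance_explained), 1, tolerance = 1e-8)
  cp <- crossprod(pca$scores[, 1:5])
  expect_lt(max(abs(cp - diag(diag(cp)))), 1e-8)

  # samples identical up to scale: all correlations 1, PC1 carries everything
  base <- rnorm(50)
  Y2 <- outer(c(1, 2, 3, 0.5), base)
  pca2 <- sample_correlation_pca(Y2)
  expect_equal(pca2$variance_explained[1], 1, tolerance = 1e-8)

  expect_error(sample_correlation_pca(rbind(rep(1, 10), rnorm(10), rnorm(10))), "constant")
})

test_that("Welch test matches the textbook formula", {
  out <- welch_t_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(out$statistic, -3.674, tolerance = 1e-3)
  expect_equal(out$df, 4.0, tolerance = 1e-8)
  expect_equal(out$p, 0.0214, tolerance = 1e-2)

  # identical groups
  same <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  # equal n, equal variances: df = n1 + n2 - 2
  x <- c(1, 2, 3, 4); y <- c(2, 3, 4, 5)
  expect_equal(welch_t_test(x, y)$df, 6, tolerance = 1e-10)

  # zero variance in both groups, equal means
  expect_equal(welch_t_test(c(2, 2), c(2, 2))$p, 1)
})

test_that("permutation set enrichment has exact degenerate behavior and recovers planted folds", {
  de <- tiny_de()
  # whole background: fold exactly 1
  whole <- set_enrichment_permutation(de, de$gene, "Western", n_perm = 1000, n_boot = 500)
  expect_equal(whole$fold_enrichment, 1.0, tolerance = 1e-12)
  # disjoint from the direction genes: fold 0
  ns_genes <- de$gene[de$direction == "NS"]
  disj <- set_enrichment_permutation(de, head(ns_genes, 20), "Western",
                                     n_perm = 1000, n_boot = 500)
  expect_equal(disj$fold_enrichment, 0)
  expect_error(set_enrichment_permutation(de, character(0), "Western"), "empty")

  # planted 2x enrichment, mean over 20 constructed backgrounds
  set.seed(41)
  folds <- replicate(20, {
    G <- 1000; nD <- 300
    dir_genes <- sample(G, nD)
    fake <- tibble::tibble(gene = paste0("g", 1:G),
                           direction = ifelse(seq_len(G) %in% dir_genes, "Western", "NS"))
    # set with twice the background direction rate
    n_set <- 100
    k <- round(2 * (nD / G) * n_set)
    members <- c(paste0("g", sample(dir_genes, k)),
                 paste0("g", sample(setdiff(1:G, dir_genes), n_set - k)))
    set_enrichment_permutation(fake, members, "Western", n_perm = 500, n_boot = 200,
                               seed = sample.int(1e6, 1))$fold_enrichment
  })
  expect_equal(mean(folds), 2.0, tolerance = 0.15)
})

test_that("Fisher enrichment equals hypergeometric enumeration", {
  # table [[3,1],[1,3]]: classic two-sided p = 17/35
  bg <- paste0("g", 1:8)
  hits <- bg[1:4]
  set <- bg[c(1, 2, 3, 5)]
  out <- fisher_set_enrichment(hits, bg, set)
  expect_equal(out$p, 17 / 35, tolerance = 1e-10)

  # hits = background: degenerate margin
  expect_equal(fisher_set_enrichment(bg, bg, set)$p, 1)

  # agreement with the hypergeometric-tail oracle on all small tables
  set.seed(42)
  for (i in 1:20) {
    N <- sample(8:30, 1)
    bgx <- paste0("g", seq_len(N))
    hitsx <- sample(bgx, sample(1:(N - 1), 1))
    setx <- sample(bgx, sample(1:(N - 1), 1))
    p_pkg <- fisher_set_enrichment(hitsx, bgx, setx)$p
    tab <- table(factor(bgx %in% setx, c(TRUE, FALSE)), factor(bgx %in% hitsx, c(TRUE, FALSE)))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    # enumeration: sum hypergeometric probabilities <= observed table's
    m <- sum(tab[1, ]); nn <- sum(tab[2, ]); kk <- sum(tab[, 1])
    support <- max(0, kk - nn):min(kk, m)
    probs <- dhyper(support, m, nn, kk)
    p_oracle <- sum(probs[probs <= dhyper(tab[1, 1], m, nn, kk) * (1 + 1e-7)])
    expect_equal(p_pkg, p_oracle, tolerance = 1e-8)
  }

  # planted 3x enrichment is detected with high power
  set.seed(43)
  hitsig <- replicate(100, {
    G <- 500; bgx <- paste0("g", 1:G)
    dirx <- rbinom(G, 1, ifelse(seq_len(G) <= 60, 0.6, 0.2)) == 1
    fisher_set_enrichment(bgx[dirx], bgx, bgx[1:60])$p < 0.05
  })
  expect_gte(mean(hitsig), 0.9)
})

test_that("CTRA category scores compare between diets as expected", {
  set.seed(44)
  n <- 35; G <- 60
  d01 <- rep(c(1, 0), c(20, 15))
  diet <- ifelse(d01 == 1, "Western", "Mediterranean")
  genes <- paste0("g", 1:G)

  # identical expression across animals: p = 1
  Y0 <- matrix(5, n, G, dimnames = list(NULL, genes))
  out0 <- ctra_score_compare(Y0, list(pro = genes[1:10]), diet)
  expect_equal(out0$p, 1)

  # +1 SD shift of the pro-inflammatory set in Western animals: high power
  hits <- replicate(100, {
    Y <- matrix(rnorm(n * G), n, G, dimnames = list(NULL, genes))
    Y[, 1:10] <- Y[, 1:10] + d01 * 1
    ctra_score_compare(Y, list(pro = genes[1:10]), diet)$p < 0.05
  })
  expect_gte(mean(hits), 0.95)
  expect_error(ctra_score_compare(Y0, list(pro = c("absent1")), diet), "present")
})

test_that("Western effect magnitudes exceed Mediterranean in rank tests on generator truth", {
  hits <- vapply(1:10, function(s) {
    st <- simulate_study(sim_config(n_genes = 800, n_true_de = 400, n_diffcor_pairs = 10,
                                    seed = 600 + s))
    tr <- st$truth$gene_truth
    w <- abs(tr$beta_true[tr$direction_true == "Western"])
    m <- abs(tr$beta_true[tr$direction_true == "Mediterranean"])
    wilcox.test(w, m, alternative = "greater")$p.value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
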