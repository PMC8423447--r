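fake_de <- function(G = 200, n_sig = 160, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    gene = sprintf("g%04d", 1:G),
    beta_diet = rnorm(G),
    se = runif(G, 0.05, 0.2),
    statistic = rnorm(G),
    p = runif(G),
    fdr = c(runif(n_sig, 0, 0.04), runif(G - n_sig, 0.06, 1)),
    direction = "Western"
  )
}

test_that("top-DEG selection is deterministic with the documented ranking", {
  de <- fake_de()
  ps <- select_top_degs(de, k = 140)
  expect_length(ps$genes, 140)
  expect_equal(nrow(ps$pairs), 9730)
  expect_identical(select_top_degs(de, k = 140)$genes, ps$genes)

  expect_equal(nrow(select_top_degs(de, k = 3)$pairs), 3)
  expect_error(select_top_degs(de, k = 190), "only 160")

  # ties on fdr break by |beta| descending then gene id
  de2 <- de
  de2$fdr[1:10] <- 0
  de2$beta_diet[1:10] <- c(5, 4, 4, 3, 2, 1, 1, 1, 1, 1)
  top <- select_top_degs(de2, k = 3)$genes
  pool <- de2$gene[1:10]
  expect_identical(top, pool[order(-abs(de2$beta_diet[1:10]), pool)][1:3])
})

test_that("individual-level products reproduce within-group Pearson correlations", {
  set.seed(50)
  n <- 35
  diet <- rep(c("Western", "Mediterranean"), c(20, 15))
  G <- 12
  Y <- matrix(rnorm(n * G), n, G, dimnames = list(NULL, sprintf("g%04d", 1:G)))
  Y[, 2] <- Y[, 1] # identical pair
  ps <- list(genes = colnames(Y),
             pairs = tibble::tibble(pair_id = sprintf("pair%05d", seq_len(choose(G, 2))),
                                    gene_i = colnames(Y)[utils::combn(G, 2)[1, ]],
                                    gene_j = colnames(Y)[utils::combn(G, 2)[2, ]]))
  class(ps) <- "gene_pair_set"
  pm <- cilp_products(Y, ps, diet)
  d01 <- diet == "Western"

  # z-standardization within each group
  zw <- pm$products[d01, ]
  # identical genes: mean product with n-1 denominator equals 1
  id_pair <- pm$group_means_r$pair_id[pm$group_means_r$gene_i == "g0001" &
                                        pm$group_means_r$gene_j == "g0002"]
  expect_equal(sum(pm$products[d01, id_pair]) / (sum(d01) - 1), 1, tolerance = 1e-10)

  # every pair: group mean product equals that group's Pearson r, machine precision
  for (k in sample(nrow(pm$group_means_r), 10)) {
    gi <- pm$group_means_r$gene_i[k]; gj <- pm$group_means_r$gene_j[k]
    expect_equal(pm$group_means_r$r_western[k], cor(Y[d01, gi], Y[d01, gj]), tolerance = 1e-10)
    expect_equal(pm$group_means_r$r_mediterranean[k], cor(Y[!d01, gi], Y[!d01, gj]), tolerance = 1e-10)
  }

  # zero within-group variance: pair flagged and excluded
  Y2 <- Y; Y2[d01, 3] <- 7
  expect_warning(pm2 <- cilp_products(Y2, ps, diet), "zero within-group variance")
  expect_false(any(pm2$group_means_r$gene_i == "g0003" | pm2$group_means_r$gene_j == "g0003"))
})

test_that("planted correlations are recovered within sampling error", {
  set.seed(51)
  n <- 35
  diet <- rep(c("Western", "Mediterranean"), c(20, 15))
  d01 <- diet == "Western"
  r_err <- replicate(20, {
    x <- rnorm(n); e <- rnorm(n)
    y <- ifelse(d01, 0.6 * x + sqrt(1 - 0.36) * e, -0.6 * x + sqrt(1 - 0.36) * e)
    Y <- cbind(g0001 = x, g0002 = y, g0003 = rnorm(n))
    ps <- list(genes = colnames(Y),
               pairs = tibble::tibble(pair_id = "pair00001", gene_i = "g0001", gene_j = "g0002"))
    class(ps) <- "gene_pair_set"
    pm <- cilp_products(Y, ps, diet)
    c(pm$group_means_r$r_western - 0.6, pm$group_means_r$r_mediterranean + 0.6)
  })
  expect_lt(max(abs(rowMeans(r_err))), 0.2)
})

test_that("the CILP mixed-model test is null-uniform and detects correlation flips", {
  set.seed(52)
  n <- 35
  diet <- rep(c("Western", "Mediterranean"), c(20, 15))
  K <- simulate_kinship(n, 12, seed = 52)

  # null pairs (disjoint, so p-values are independent): approximately uniform
  G <- 500
  Y <- matrix(rnorm(n * G), n, G, dimnames = list(NULL, sprintf("g%04d", 1:G)))
  ps <- structure(list(
    genes = colnames(Y),
    pairs = tibble::tibble(pair_id = sprintf("pair%05d", 1:250),
                           gene_i = colnames(Y)[seq(1, G - 1, 2)],
                           gene_j = colnames(Y)[seq(2, G, 2)])
  ), class = "gene_pair_set")
  pm <- cilp_products(Y, ps, diet)
  res <- suppressMessages(cilp_test(pm, diet, K, n_perm = 20, seed = 1))
  expect_true(all(res$p >= 0 & res$p <= 1))
  ks <- suppressWarnings(ks.test(res$p, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_true(all(c("pair_id", "beta_diet_product", "fdr", "r_western",
                    "r_mediterranean") %in% names(res)))

  # type-I error of the product test at nominal p < 0.05 stays near nominal
  X <- cbind(1, diet = as.numeric(diet == "Western"))
  rates <- vapply(1:10, function(s) {
    set.seed(900 + s)
    Yn <- matrix(rnorm(n * G), n, G, dimnames = list(NULL, colnames(Y)))
    pmn <- cilp_products(Yn, ps, diet)
    core <- dietfx:::lmm_core(pmn$products, X, dietfx:::lmm_eigen(K), refine = FALSE)
    mean(core$p["diet", ] < 0.05)
  }, numeric(1))
  expect_lt(abs(mean(rates) - 0.05), 0.02)

  # a planted +0.6 / -0.6 flip is detected at p < 0.05 most of the time (smoke run;
  # the full power characterization lives with the acceptance checks)
  hits <- replicate(20, {
    x <- rnorm(n); e <- rnorm(n)
    d01 <- diet == "Western"
    y <- ifelse(d01, 0.6 * x + sqrt(1 - 0.36) * e, -0.6 * x + sqrt(1 - 0.36) * e)
    Y1 <- cbind(g0001 = x, g0002 = y)
    ps1 <- list(genes = colnames(Y1),
                pairs = tibble::tibble(pair_id = "pair00001", gene_i = "g0001", gene_j = "g0002"))
    class(ps1) <- "gene_pair_set"
    pm1 <- cilp_products(Y1, ps1, diet)
    fit <- fit_lmm(pm1$products[, 1], cbind(1, diet = as.numeric(d01)), K)
    fit$p["diet"] < 0.05
  })
  expect_gte(mean(hits), 0.7)
})

test_that("hub detection matches the hypergeometric null and flags planted hubs", {
  de <- fake_de(G = 60, n_sig = 60)
  ps <- select_top_degs(de, k = 20) # 190 pairs

  # no significant pairs: no hubs
  none <- detect_hubs(character(0), ps)
  expect_length(none$hub_genes, 0)

  # partner counts sum to twice the significant pair count
  sig <- ps$pairs$pair_id[1:40]
  h <- detect_hubs(sig, ps, n_resample = 200, seed = 2)
  expect_equal(sum(h$partner_counts$observed), 2 * length(sig))

  # Monte-Carlo pooled percentile against the closed-form hypergeometric quantile
  q_mc <- h$null_quantile
  q_hyper <- qhyper(0.95, 19, choose(20, 2) - 19, 40)
  expect_lte(abs(ceiling(q_mc) - q_hyper), 1)

  # a gene carrying far more partners than the null mean is flagged
  set.seed(53)
  flagged <- replicate(20, {
    focal_pairs <- ps$pairs$pair_id[ps$pairs$gene_i == ps$genes[1] |
                                      ps$pairs$gene_j == ps$genes[1]]
    other <- setdiff(ps$pairs$pair_id, focal_pairs)
    sigx <- c(focal_pairs[1:15], sample(other, 25))
    hx <- detect_hubs(sigx, ps, n_resample = 300, seed = sample.int(1e6, 1))
    ps$genes[1] %in% hx$hub_genes
  })
  expect_gte(mean(flagged), 0.95)
  expect_error(detect_hubs("nope", ps), "subset")
})

test_that("hypergeometric TF enrichment agrees with the closed form", {
  bg <- paste0("g", 1:140)
  tf <- bg[1:70]
  hubs <- bg[1:10] # all hubs are TFs
  out <- hypergeom_tf_enrichment(hubs, bg, tf)
  expect_equal(out$p, phyper(9, 70, 70, 10, lower.tail = FALSE), tolerance = 1e-12)
  # all-TF hubs against a half-TF background: p = choose(K, n)/choose(N, n)
  expect_equal(out$p, choose(70, 10) / choose(140, 10), tolerance = 1e-10)

  # null-rate hubs are unremarkable
  set.seed(54)
  ps <- replicate(30, {
    hubsx <- sample(bg, 10)
    hypergeom_tf_enrichment(hubsx, bg, tf)$p
  })
  expect_gte(mean(ps >= 0.3), 0.5)
  expect_error(hypergeom_tf_enrichment(hubs, bg, paste0("x", 1:5)), "overlap")
})
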