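obs_row <- function(animal, session, behavior, kind, value, phase = "experimental",
                    secs = 600) {
  tibble::tibble(animal_id = animal, session_id = session, phase = phase,
                 behavior = behavior, kind = kind, value = value,
                 session_seconds = secs)
}

test_that("focal observations summarize to rates and proportions", {
  # 300 s of body contact in one 600 s session: proportion 0.5
  obs <- obs_row("a1", "s1", "body_contact", "state", 300)
  out <- summarize_focal_observations(obs)
  expect_equal(out$value[out$behavior == "body_contact"], 0.5)
  expect_equal(out$hours_observed[1], 600 / 3600)

  # 3 aggression events over two 600 s sessions: 9 events/hour
  obs2 <- dplyr::bind_rows(
    obs_row("a1", "s1", "contact_aggression", "event", 2),
    obs_row("a1", "s2", "noncontact_aggression", "event", 1)
  )
  out2 <- summarize_focal_observations(obs2)
  expect_equal(out2$value[out2$behavior == "aggression"], 9.0)

  # aggregation over sessions equals aggregation over pooled seconds
  obs3a <- dplyr::bind_rows(
    obs_row("a1", "s1", "rest", "state", 100),
    obs_row("a1", "s2", "rest", "state", 500)
  )
  obs3b <- obs_row("a1", "s1", "rest", "state", 600, secs = 1200)
  expect_equal(summarize_focal_observations(obs3a)$value,
               summarize_focal_observations(obs3b)$value)

  # unknown codes are reported and excluded
  mp <- default_behavior_mapping("rest")
  expect_warning(out4 <- summarize_focal_observations(
    dplyr::bind_rows(obs_row("a1", "s1", "rest", "state", 100),
                     obs_row("a1", "s1", "mystery", "event", 2)), mapping = mp),
    "mystery")
  expect_false("mystery" %in% out4$behavior)
})

test_that("Mann-Whitney U equals full enumeration for small samples", {
  # x = [1,2], y = [3,4]: U = 0, exact two-sided p = 2/6
  out <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(out$statistic, 0)
  expect_equal(out$p, 1 / 3, tolerance = 1e-12)

  # all tied: U = nx ny / 2, p = 1
  tied <- mann_whitney_u(c(2, 2, 2), c(2, 2))
  expect_equal(tied$statistic, 3)
  expect_equal(tied$p, 1)

  set.seed(60)
  for (i in 1:30) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    x <- sample(seq(1, 100), nx) + runif(nx) # no ties
    y <- sample(seq(101, 200), ny) * runif(ny)
    out <- mann_whitney_u(x, y)
    expect_equal(out$p, mw_exact_oracle(x, y), tolerance = 1e-10)
    # U_x + U_y = nx * ny
    expect_equal(out$statistic + mann_whitney_u(y, x)$statistic, nx * ny)
  }
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("Holm adjustment equals brute-force sequential rejection", {
  expect_equal(holm_bonferroni(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06), tolerance = 1e-12)
  expect_equal(holm_bonferroni(0.2), 0.2)
  expect_error(holm_bonferroni(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(61)
  for (i in 1:10) {
    p <- runif(sample(3:12, 1))
    adj <- holm_bonferroni(p)
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(adj <= 1))
    # decisions agree with the sequential-rejection oracle on an alpha grid
    for (alpha in c(0.01, 0.05, 0.1, 0.25, 0.5)) {
      expect_identical(adj <= alpha, holm_reject_oracle(p, alpha))
    }
  }
})

test_that("behavior PCA recovers a planted diet-linked factor as the DAB axis", {
  study <- tiny_study()
  beh <- summarize_focal_observations(study$behavior, phase = "experimental")
  diet <- setNames(study$metadata$diet, study$metadata$animal_id)
  dab <- suppressWarnings(behavior_pca_dab(beh, diet))

  truth <- study$truth$dab
  merged <- dplyr::left_join(dab$dab, truth, by = "animal_id")
  expect_gte(abs(cor(merged$dab, merged$dab_true)), 0.9)

  # orientation: body contact loads positively, so Mediterranean animals are higher
  expect_gte(dab$loadings["body_contact", dab$dab_component], 0)
  med <- merged$dab[diet[merged$animal_id] == "Mediterranean"]
  wes <- merged$dab[diet[merged$animal_id] == "Western"]
  expect_gt(mean(med), mean(wes))

  # reconstruction of the scaled behavior matrix
  recon <- dab$scores %*% t(dab$loadings)
  expect_lt(max(abs(recon - dab$scaled_matrix)), 1e-8)

  # two perfectly correlated behaviors: PC1 explains everything
  two <- tibble::tibble(
    animal_id = rep(sprintf("a%02d", 1:10), 2),
    behavior = rep(c("b1", "b2"), each = 10),
    kind = "state", value = rep(seq(0.1, 1, 0.1), 2) * c(rep(1, 10), rep(2, 10))
  )
  d2 <- setNames(rep(c("Western", "Mediterranean"), 5), sprintf("a%02d", 1:10))
  pc2 <- suppressWarnings(behavior_pca_dab(two, d2, anchor_behavior = "b1"))
  expect_equal(pc2$variance_explained[1], 1, tolerance = 1e-8)
})

test_that("baseline phase shows no diet differences after Holm", {
  # Holm controls the familywise error at 5%, so >= 95% of seeds are expected
  # clean; the bound below leaves room for binomial noise at 30 seeds
  clean <- vapply(1:30, function(s) {
    st <- simulate_study(sim_config(n_genes = 30, n_true_de = 10, n_diffcor_pairs = 2,
                                    seed = 700 + s))
    beh <- summarize_focal_observations(st$behavior, phase = "baseline")
    diet <- setNames(st$metadata$diet, st$metadata$animal_id)
    p <- vapply(split(beh, beh$behavior), function(bb) {
      mann_whitney_u(bb$value[diet[bb$animal_id] == "Western"],
                     bb$value[diet[bb$animal_id] == "Mediterranean"])$p
    }, numeric(1))
    all(holm_bonferroni(p) >= 0.05)
  }, logical(1))
  expect_gte(mean(clean), 0.9)
})

test_that("behavior-DAB correlations behave at the extremes", {
  study <- tiny_study()
  beh <- summarize_focal_observations(study$behavior, phase = "experimental")
  diet <- setNames(study$metadata$diet, study$metadata$animal_id)
  dab <- suppressWarnings(behavior_pca_dab(beh, diet))

  # a behavior identical to the DAB score correlates perfectly
  synth <- dplyr::bind_rows(beh, tibble::tibble(
    animal_id = dab$dab$animal_id, behavior = "dab_copy", kind = "state",
    value = dab$dab$dab, hours_observed = 4))
  cors <- dab_behavior_correlations(synth, dab)
  expect_equal(cors$r[cors$behavior == "dab_copy"], 1.0, tolerance = 1e-10)

  # independent noise stays well below |r| = 0.45 for n = 35
  set.seed(62)
  null_r <- replicate(40, {
    noise <- tibble::tibble(animal_id = dab$dab$animal_id, behavior = "noise",
                            kind = "state", value = rnorm(nrow(dab$dab)),
                            hours_observed = 4)
    dab_behavior_correlations(noise, dab)$r
  })
  expect_gte(mean(abs(null_r) < 0.45), 0.95)

  # constant behavior flagged
  const <- tibble::tibble(animal_id = dab$dab$animal_id, behavior = "flat",
                          kind = "state", value = 1, hours_observed = 4)
  expect_warning(out <- dab_behavior_correlations(const, dab), "constant")
  expect_true(is.na(out$r[out$behavior == "flat"]))
})
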