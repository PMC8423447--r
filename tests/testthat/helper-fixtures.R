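# shared fixtures: one small synthetic study, preprocessed once per run
tiny_cache <- new.env(parent = emptyenv())

tiny_study <- function() {
  if (is.null(tiny_cache$study)) {
    tiny_cache$study <- suppressMessages(simulate_study(sim_config(
      n_genes = 400, n_true_de = 160, n_diffcor_pairs = 10,
      n_sessions_experimental = 24, seed = 101
    )))
  }
  tiny_cache$study
}

tiny_prep <- function() {
  if (is.null(tiny_cache$resid)) {
    study <- tiny_study()
    filtered <- suppressMessages(filter_low_expression(study$counts))
    norm <- normalize_logcpm_weights(filtered)
    tiny_cache$resid <- residualize_covariates(
      norm, study$metadata[, c("CD14", "CD3", "RIN", "concentration")])
  }
  tiny_cache$resid
}

tiny_de <- function() {
  if (is.null(tiny_cache$de)) {
    study <- tiny_study()
    tiny_cache$de <- suppressMessages(run_de(
      tiny_prep(), study$metadata$diet, study$kinship, n_perm = 50, seed = 7))
  }
  tiny_cache$de
}

# full-enumeration Mann-Whitney oracle (no ties), two-sided
mw_exact_oracle <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  splits <- utils::combn(length(pooled), nx)
  Us <- apply(splits, 2, function(ii) sum(r[ii]) - nx * (nx + 1) / 2)
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  min(1, 2 * min(mean(Us <= u), mean(Us >= u)))
}

# brute-force Holm decisions: sequential rejection at alpha / (m - i + 1)
holm_reject_oracle <- function(p, alpha) {
  ord <- order(p)
  m <- length(p)
  reject <- logical(m)
  for (i in seq_len(m)) {
    if (p[ord[i]] <= alpha / (m - i + 1)) reject[ord[i]] <- TRUE else break
  }
  reject
}

# ordinary least squares reference fit (coefficient 2 = effect of interest)
ols_reference <- function(y, x) {
  s <- summary(lm(y ~ x))$coefficients
  list(beta = s[2, 1], se = s[2, 2], p = s[2, 4])
}
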