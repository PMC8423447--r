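#' Pipeline configuration
#'
#' Bundles either a simulation block or paths to input files with the stage
#' parameters of the full analysis. Thresholds must lie in (0, 1); referenced
#' files are checked at run time.
#'
#' @param simulate a [sim_config()] to generate the study, or `NULL` to load
#'   from files.
#' @param paths named list of input files (`counts`, `metadata`, `kinship`,
#'   `gene_sets`, `behavior`) when `simulate` is `NULL`; a fixture directory
#'   written by [write_fixture()] may be given as `fixture_dir`.
#' @param n_perm diet permutations for the DE, CILP and gating stages.
#' @param fdr_de,fdr_cilp,fdr_gate empirical FDR thresholds.
#' @param k_top_degs genes entering the co-expression stage (capped at the
#'   number of significant genes).
#' @param n_boot bootstrap iterations for mediation.
#' @param marker_gene contamination marker gene id (`NULL` disables the
#'   check).
#' @param marker_k MAD multiplier for the contamination rule.
#' @param out_dir output directory.
#' @param seed global seed; stage seeds derive from it by fixed offsets.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = sim_config(), paths = NULL,
                            n_perm = 100, fdr_de = 0.05, fdr_cilp = 0.2,
                            fdr_gate = 0.05, k_top_degs = 140, n_boot = 1000,
                            marker_gene = "CD3E", marker_k = 5,
                            out_dir = tempfile("dietfx_run_"), seed = 1) {
  for (thr in c(fdr_de, fdr_cilp, fdr_gate)) {
    if (thr <= 0 || thr >= 1) abort("FDR thresholds must lie in (0, 1)")
  }
  structure(list(
    simulate = simulate, paths = paths,
    n_perm = assert_count(n_perm, "n_perm"),
    fdr_de = fdr_de, fdr_cilp = fdr_cilp, fdr_gate = fdr_gate,
    k_top_degs = assert_count(k_top_degs, "k_top_degs"),
    n_boot = assert_count(n_boot, "n_boot"),
    marker_gene = marker_gene, marker_k = marker_k,
    out_dir = out_dir, seed = assert_count(seed, "seed", positive = FALSE)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML may contain a `simulate:` block (passed to [sim_config()]) and
#' any [pipeline_config()] field.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) y$simulate <- do.call(sim_config, y$simulate)
  do.call(pipeline_config, y)
}

#' @keywords internal
load_study_inputs <- function(config) {
  if (!is.null(config$simulate)) {
    return(simulate_study(config$simulate))
  }
  p <- config$paths
  if (!is.null(p$fixture_dir)) return(read_fixture(p$fixture_dir))
  for (f in unlist(p)) if (!file.exists(f)) abort(paste0("input file not found: ", f))
  list(
    counts = read_counts_tsv(p$counts),
    metadata = read_tsv_plain(p$metadata),
    kinship = read_kinship_tsv(p$kinship),
    gene_sets = read_gmt(p$gene_sets),
    behavior = read_tsv_plain(p$behavior),
    truth = NULL, config = NULL
  )
}

#' Run the full pipeline
#'
#' Executes the stages in order -- simulate/load, preprocess (filter,
#' normalize, contamination check, covariate residualization), differential
#' expression with expression PCA and gene-set enrichment, CILP differential
#' co-expression with hub detection and TF enrichment, behavior summary with
#' the DAB composite, and bidirectional mediation -- writing every result
#' table as TSV plus a machine-readable manifest. Each table's header records
#' the seed and parameters that produced it. A stage failure is recorded in
#' the manifest and downstream stages are skipped.
#'
#' @param config a [pipeline_config()].
#' @return the manifest tibble (`stage`, `status`, `seconds`, `outputs`,
#'   `input_hash`), invisibly; all tables under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  prov <- function(stage, extra = "") {
    c(sprintf("stage=%s seed=%d n_perm=%d fdr_de=%g fdr_cilp=%g fdr_gate=%g n_boot=%d%s",
              stage, config$seed, config$n_perm, config$fdr_de, config$fdr_cilp,
              config$fdr_gate, config$n_boot, extra))
  }
  manifest <- list()
  input_hash <- if (!is.null(config$simulate)) {
    digest_config(config$simulate)
  } else {
    paste(tools::md5sum(unlist(config$paths)), collapse = ",")
  }
  note <- function(stage, status, secs, outputs) {
    manifest[[length(manifest) + 1L]] <<- tibble(
      stage = stage, status = status, seconds = round(secs, 2),
      outputs = paste(outputs, collapse = ";"), input_hash = input_hash
    )
  }
  run_stage <- function(stage, fn) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fn(), error = function(e) e)
    secs <- proc.time()[["elapsed"]] - t0
    if (inherits(res, "error")) {
      note(stage, paste0("failed: ", conditionMessage(res)), secs, character(0))
      NULL
    } else {
      note(stage, "ok", secs, res$outputs %||% character(0))
      res
    }
  }

  ## stage 1: study ----
  st <- run_stage("load", function() {
    study <- load_study_inputs(config)
    list(study = study, outputs = character(0))
  })
  state <- new.env(parent = emptyenv())
  ok <- !is.null(st)
  if (ok) state$study <- st$study

  ## stage 2: preprocess ----
  if (ok) ok <- !is.null(run_stage("preprocess", function() {
    study <- state$study
    filtered <- filter_low_expression(study$counts)
    norm <- normalize_logcpm_weights(filtered)
    flagged <- character(0)
    if (!is.null(config$marker_gene) && config$marker_gene %in% norm$gene_ids) {
      flagged <- flag_marker_contamination(norm, config$marker_gene, k = config$marker_k)
    }
    keep <- setdiff(norm$sample_ids, flagged)
    meta <- filter(as_tibble(study$metadata), .data$animal_id %in% keep)
    meta <- arrange(meta, match(.data$animal_id, norm$sample_ids))
    if (length(flagged) > 0) {
      norm$logcpm <- norm$logcpm[keep, , drop = FALSE]
      norm$weights <- norm$weights[keep, , drop = FALSE]
      norm$sample_ids <- keep
    }
    resid <- residualize_covariates(norm, meta[, c("CD14", "CD3", "RIN", "concentration")])
    qc <- tibble(sample_id = norm$sample_ids, flagged = FALSE)
    qc <- bind_rows(qc, tibble(sample_id = flagged, flagged = TRUE))
    write_tsv_plain(qc, out("qc_samples.tsv"), prov("preprocess"))
    state$resid <- resid
    state$meta <- meta
    state$K <- kinship_matrix(unclass(state$study$kinship)[meta$animal_id, meta$animal_id])
    list(outputs = "qc_samples.tsv")
  }))

  ## stage 3: differential expression + PCA + enrichment ----
  if (ok) ok <- !is.null(run_stage("de", function() {
    de <- run_de(state$resid, state$meta$diet, state$K, n_perm = config$n_perm,
                 fdr_threshold = config$fdr_de, seed = child_seed(config$seed, 31))
    write_tsv_plain(de, out("de_results.tsv"), prov("de"))
    pca <- sample_correlation_pca(state$resid, state$meta$diet)
    write_tsv_plain(as_tibble(pca$scores, rownames = "animal_id"), out("pca_scores.tsv"), prov("de"))
    state$de <- de
    state$pca <- pca
    list(outputs = c("de_results.tsv", "pca_scores.tsv"))
  }))

  if (ok) run_stage("enrich", function() {
    sets <- state$study$gene_sets
    rows <- list()
    for (nm in intersect(c("M1", "M2"), names(sets))) {
      for (dd in c("Western", "Mediterranean")) {
        rows[[paste(nm, dd)]] <- mutate(
          set_enrichment_permutation(state$de, intersect(sets[[nm]], state$de$gene),
                                     direction = dd, n_perm = 1e4, n_boot = 2e3,
                                     seed = child_seed(config$seed, 41), set_name = nm),
          direction = dd)
      }
    }
    hits_w <- state$de$gene[state$de$direction == "Western"]
    for (nm in grep("^trait_", names(sets), value = TRUE)) {
      rows[[nm]] <- mutate(fisher_set_enrichment(hits_w, state$de$gene, sets[[nm]], set_name = nm),
                           direction = "Western")
    }
    enr <- bind_rows(rows)
    write_tsv_plain(enr, out("enrichment.tsv"), prov("enrich"))
    ctra_sets <- sets[grep("^CTRA_", names(sets))]
    ctra <- ctra_score_compare(state$resid, lapply(ctra_sets, intersect, colnames(resid_matrix(state$resid))),
                               state$meta$diet)
    write_tsv_plain(ctra, out("ctra.tsv"), prov("enrich"))
    list(outputs = c("enrichment.tsv", "ctra.tsv"))
  })

  ## stage 4: CILP ----
  if (ok) run_stage("cilp", function() {
    n_sig <- sum(state$de$fdr < config$fdr_de)
    k <- min(config$k_top_degs, n_sig)
    pairset <- select_top_degs(state$de, k = k, fdr_threshold = config$fdr_de)
    prods <- cilp_products(state$resid, pairset, state$meta$diet)
    cilp <- cilp_test(prods, state$meta$diet, state$K, n_perm = config$n_perm,
                      fdr_threshold = config$fdr_cilp, seed = child_seed(config$seed, 51))
    write_tsv_plain(cilp, out("cilp_results.tsv"), prov("cilp", sprintf(" k=%d", k)))
    hubs <- detect_hubs(cilp, pairset, seed = child_seed(config$seed, 52))
    write_tsv_plain(mutate(hubs$partner_counts,
                           hub = .data$gene %in% hubs$hub_genes,
                           threshold = hubs$threshold),
                    out("hubs.tsv"), prov("cilp"))
    if ("TF" %in% names(state$study$gene_sets) && length(hubs$hub_genes) > 0) {
      tf <- hypergeom_tf_enrichment(hubs$hub_genes, pairset$genes, state$study$gene_sets$TF)
      write_tsv_plain(tf, out("tf_enrichment.tsv"), prov("cilp"))
    }
    state$cilp <- cilp
    state$hubs <- hubs
    list(outputs = c("cilp_results.tsv", "hubs.tsv"))
  })

  ## stage 5: behavior ----
  if (ok) ok <- !is.null(run_stage("behavior", function() {
    beh <- summarize_focal_observations(state$study$behavior, phase = "experimental")
    beh <- filter(beh, .data$animal_id %in% state$meta$animal_id)
    write_tsv_plain(beh, out("behavior_summary.tsv"), prov("behavior"))
    diet <- setNames(state$meta$diet, state$meta$animal_id)
    tests <- beh |>
      group_by(.data$behavior, .data$kind) |>
      summarise(mw = list(mann_whitney_u(.data$value[diet[.data$animal_id] == "Western"],
                                         .data$value[diet[.data$animal_id] == "Mediterranean"])),
                .groups = "drop") |>
      tidyr::unnest("mw")
    tests <- mutate(tests, p_holm = holm_bonferroni(tests$p))
    write_tsv_plain(tests, out("behavior_tests.tsv"), prov("behavior"))
    dab <- behavior_pca_dab(beh, diet)
    write_tsv_plain(dab$dab, out("dab_scores.tsv"), prov("behavior"))
    write_tsv_plain(dab_behavior_correlations(beh, dab), out("dab_correlations.tsv"), prov("behavior"))
    write_tsv_plain(glance(dab), out("dab_summary.tsv"), prov("behavior"))
    state$dab <- dab
    list(outputs = c("behavior_summary.tsv", "behavior_tests.tsv", "dab_scores.tsv",
                     "dab_correlations.tsv", "dab_summary.tsv"))
  }))

  ## stage 6: mediation ----
  if (ok) run_stage("mediate", function() {
    gate <- gate_univariate_association(state$resid, state$dab, state$K,
                                        n_perm = config$n_perm, fdr_threshold = config$fdr_gate,
                                        seed = child_seed(config$seed, 61))
    write_tsv_plain(gate, out("mediation_gate.tsv"), prov("mediate"))
    deg <- state$de$gene[state$de$direction != "NS"]
    gated <- intersect(gate$gene[gate$significant], deg)
    outputs <- "mediation_gate.tsv"
    if (length(gated) > 0) {
      sp <- boot_spec(config$n_boot, 90, seed = child_seed(config$seed, 62))
      for (dd in c("forward", "reverse")) {
        scan <- mediation_scan(state$resid, state$meta$diet, state$dab, gated,
                               direction = dd, spec = sp, de = state$de)
        f <- paste0("mediation_", dd, ".tsv")
        write_tsv_plain(scan, out(f), prov("mediate"))
        outputs <- c(outputs, f)
      }
    }
    list(outputs = outputs)
  })

  manifest <- bind_rows(manifest)
  readr::write_tsv(manifest, out("manifest.tsv"))
  write_report(config$out_dir)
  invisible(manifest)
}

#' @keywords internal
digest_config <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(cfg), tmp)
  unname(tools::md5sum(tmp))
}

#' Write a plain-text summary report for a pipeline run
#'
#' Regenerates `report.txt` (and `report_deg_counts.tsv`) from the result
#' tables in an output directory: DEG counts by direction (conserved against
#' the total), enrichment, CILP pair and hub counts, behavior tests, the DAB
#' diet association and the mediation summary. Missing stage outputs are
#' marked absent. Regeneration is idempotent.
#'
#' @param out_dir pipeline output directory.
#' @return path of the report, invisibly.
#' @export
write_report <- function(out_dir) {
  p <- function(f) file.path(out_dir, f)
  lines <- c("dietfx pipeline report", "======================", "")
  sect <- function(title, f, render) {
    if (file.exists(p(f))) {
      c(title, render(read_tsv_plain(p(f))), "")
    } else {
      c(title, "  [absent]", "")
    }
  }
  lines <- c(lines, sect("Differential expression", "de_results.tsv", function(de) {
    cnt <- table(factor(de$direction, levels = c("Western", "Mediterranean", "NS")))
    counts_df <- tibble(direction = names(cnt), n = as.integer(cnt))
    readr::write_tsv(counts_df, p("report_deg_counts.tsv"))
    sprintf("  %s genes: %d (total %d)", names(cnt), as.integer(cnt), nrow(de))
  }))
  lines <- c(lines, sect("Gene-set enrichment", "enrichment.tsv", function(e) {
    sprintf("  %s [%s, %s]: fold = %.2f, p = %.3g", e$set_name, e$method,
            e$direction %||% "", e$fold_enrichment, e$p)
  }))
  lines <- c(lines, sect("CTRA", "ctra.tsv", function(e) {
    sprintf("  %s (n=%d genes): U = %g, p = %.3g (Holm %.3g)", e$category, e$n_genes,
            e$statistic, e$p, e$p_adjusted)
  }))
  lines <- c(lines, sect("Differential co-expression", "cilp_results.tsv", function(cc) {
    sprintf("  %d of %d pairs significant", sum(cc$significant), nrow(cc))
  }))
  lines <- c(lines, sect("Hub genes", "hubs.tsv", function(h) {
    sprintf("  %d hub gene(s) at threshold %g partners", sum(h$hub), h$threshold[1])
  }))
  lines <- c(lines, sect("Behavior tests (experimental phase)", "behavior_tests.tsv", function(b) {
    sig <- b[b$p_holm < 0.05, ]
    c(sprintf("  %d of %d behaviors differ between diets after Holm", nrow(sig), nrow(b)),
      sprintf("    %s: U = %g, p_holm = %.3g", sig$behavior, sig$statistic, sig$p_holm))
  }))
  lines <- c(lines, sect("DAB composite", "dab_summary.tsv", function(d) {
    sprintf("  DAB = PC%d (%.0f%% variance), diet p = %.3g (Holm %.3g)",
            d$dab_component, 100 * d$variance_explained, d$p_diet, d$p_diet_holm)
  }))
  for (dd in c("forward", "reverse")) {
    lines <- c(lines, sect(paste0("Mediation (", dd, ")"), paste0("mediation_", dd, ".tsv"),
                           function(m) {
      pm <- 100 * abs(m$proportion_mediated[m$significant])
      c(sprintf("  %d of %d gated genes significant", sum(m$significant), nrow(m)),
        if (length(pm) > 0) sprintf("  mean |proportion mediated| = %.1f%% (sd %.1f%%)",
                                    mean(pm, na.rm = TRUE), sd(pm, na.rm = TRUE)))
    }))
  }
  readr::write_lines(lines, p("report.txt"))
  invisible(p("report.txt"))
}
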