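#' Default mapping from raw ethogram codes to summary behaviors
#'
#' Contact and non-contact aggression are combined into `aggression`;
#' self-directed behaviors (self-grooming and scratching) form the `anxiety`
#' index. All other codes map to themselves.
#'
#' @param codes raw behavior codes present in the data.
#' @return tibble with columns `code`, `summary`.
#' @export
default_behavior_mapping <- function(codes) {
  tibble(code = codes) |>
    mutate(summary = dplyr::case_when(
      .data$code %in% c("contact_aggression", "noncontact_aggression") ~ "aggression",
      .data$code %in% c("self_groom", "scratch") ~ "anxiety",
      TRUE ~ .data$code
    ))
}

#' Summarize focal observations into per-animal behavior measures
#'
#' Event behaviors are summarized as rates (events per hour of observation);
#' state behaviors as duration proportions (fraction of observed time).
#' Observed time per animal is the summed duration of its distinct sessions
#' in the phase, so truncated sessions are handled correctly and aggregation
#' over sessions equals aggregation over pooled seconds.
#'
#' @param observations long-format tibble with columns `animal_id`,
#'   `session_id`, `phase`, `behavior`, `kind` (`"event"`/`"state"`), `value`
#'   (count or seconds) and optionally `session_seconds` (default 600).
#' @param phase which phase to summarize (`"experimental"` or `"baseline"`).
#' @param mapping optional tibble (`code`, `summary`) mapping raw codes to
#'   summary behaviors; defaults to [default_behavior_mapping()]. Codes
#'   absent from the mapping are reported and excluded.
#' @return a tibble of class `behavior_table`: `animal_id`, `behavior`,
#'   `kind`, `value` (rate in events/h or proportion in [0, 1]),
#'   `hours_observed`.
#' @export
summarize_focal_observations <- function(observations, phase = "experimental",
                                         mapping = NULL) {
  obs <- as_tibble(observations)
  if (!"session_seconds" %in% names(obs)) obs$session_seconds <- 600
  obs <- filter(obs, .data$phase == !!phase)
  if (nrow(obs) == 0) abort(paste0("no observations in phase: ", phase))
  mapping <- mapping %||% default_behavior_mapping(unique(obs$behavior))
  unknown <- setdiff(unique(obs$behavior), mapping$code)
  if (length(unknown) > 0) {
    warn(paste0("unknown behavior code(s) excluded: ", paste(unknown, collapse = ", ")))
    obs <- filter(obs, .data$behavior %in% mapping$code)
  }
  obs <- left_join(obs, mapping, by = c(behavior = "code"))
  time_per_animal <- obs |>
    dplyr::distinct(.data$animal_id, .data$session_id, .data$session_seconds) |>
    group_by(.data$animal_id) |>
    summarise(total_seconds = sum(.data$session_seconds), .groups = "drop")
  out <- obs |>
    group_by(.data$animal_id, .data$summary, .data$kind) |>
    summarise(total = sum(.data$value), .groups = "drop") |>
    left_join(time_per_animal, by = "animal_id") |>
    mutate(
      value = ifelse(.data$kind == "event",
                     .data$total / (.data$total_seconds / 3600),
                     .data$total / .data$total_seconds),
      hours_observed = .data$total_seconds / 3600
    ) |>
    select(animal_id = "animal_id", behavior = "summary", "kind", "value", "hours_observed")
  if (any(out$value[out$kind == "state"] > 1 + 1e-9)) {
    warn("state proportions exceed 1: state seconds exceed session time")
  }
  class(out) <- c("behavior_table", class(out))
  out
}

#' Mann-Whitney U test
#'
#' U statistic from midranks (reported for the first sample), with an exact
#' two-sided p-value by enumeration when both groups are at most
#' `exact_max_n` and there are no ties, otherwise the normal approximation
#' with tie and continuity corrections.
#'
#' @param x,y numeric vectors.
#' @param exact_max_n largest group size for which the exact distribution is
#'   used (default 8).
#' @return one-row tibble: `statistic` (U of `x`), `p`, `method`.
#' @export
mann_whitney_u <- function(x, y, exact_max_n = 8) {
  if (length(x) == 0 || length(y) == 0) abort("both samples must be non-empty")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  if (length(unique(c(x, y))) == 1) {
    return(tibble(statistic = U, p = 1, method = "degenerate"))
  }
  ties <- any(duplicated(c(x, y)))
  exact <- !ties && nx <= exact_max_n && ny <= exact_max_n
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  tibble(statistic = U, p = wt$p.value,
         method = if (exact) "exact" else "normal approximation")
}

#' Holm-Bonferroni adjustment
#'
#' Step-down adjustment: with p-values sorted ascending, the i-th adjusted
#' value is the running maximum of `(m - j + 1) p_(j)` for `j <= i`, capped
#' at 1 and mapped back to the input order.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return adjusted p-values in the input order.
#' @export
holm_bonferroni <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "holm")
}

#' Behavior PCA and the diet-altered behavior (DAB) composite
#'
#' Standardizes the per-animal behavior table (columns centered, unit
#' variance), runs principal component analysis, tests every component
#' against diet with Welch's t (Holm-adjusted), and designates as the DAB
#' component the most diet-associated component among those significant
#' after adjustment. The DAB axis is oriented so the anchor behavior
#' (body contact by default) loads positively, which puts Mediterranean-type
#' affiliative behavior at the positive end.
#'
#' @param behaviors a [summarize_focal_observations()] result (long tibble).
#' @param diet diet labels, one per animal (named by animal id or aligned
#'   with the sorted animal ids of `behaviors`).
#' @param anchor_behavior behavior whose loading is forced non-negative.
#' @param alpha Holm-adjusted significance level for component selection.
#' @return an object of class `dab_scores`: `loadings`, `scores`,
#'   `variance_explained`, `component_tests`, `dab_component`, `dab` (tibble
#'   `animal_id`, `dab`).
#' @export
behavior_pca_dab <- function(behaviors, diet, anchor_behavior = "body_contact",
                             alpha = 0.05) {
  wide <- tidyr::pivot_wider(as_tibble(behaviors)[, c("animal_id", "behavior", "value")],
                             names_from = "behavior", values_from = "value")
  wide <- arrange(wide, .data$animal_id)
  if (anyNA(wide)) abort("behavior table has missing cells")
  if (nrow(wide) < 3 || ncol(wide) < 3) abort("need >= 3 animals and >= 2 behaviors")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$animal_id
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    warn(paste0("dropping zero-variance behavior(s): ",
                paste(colnames(m)[sds == 0], collapse = ", ")))
    m <- m[, sds > 0, drop = FALSE]
  }
  if (!is.null(names(diet))) diet <- diet[rownames(m)]
  d01 <- diet_to_indicator(diet)
  pc <- prcomp(m, center = TRUE, scale. = TRUE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  tests <- purrr::map_dfr(seq_len(ncol(pc$x)), function(j) {
    wt <- welch_t_test(pc$x[d01 == 1, j], pc$x[d01 == 0, j])
    mutate(wt, component = paste0("PC", j), variance_explained = ve[j], .before = 1)
  })
  tests <- mutate(tests, p_holm = holm_bonferroni(tests$p))
  sig <- which(tests$p_holm < alpha)
  if (length(sig) > 0) {
    dab_idx <- sig[which.min(tests$p[sig])]
  } else {
    dab_idx <- which.min(tests$p)
    warn("no component significant after Holm adjustment; using the most diet-associated component")
  }
  rot <- pc$rotation; sc <- pc$x
  anchor <- if (anchor_behavior %in% rownames(rot)) anchor_behavior else {
    warn(paste0("anchor behavior '", anchor_behavior, "' absent; using ", rownames(rot)[1]))
    rownames(rot)[1]
  }
  if (rot[anchor, dab_idx] < 0) {
    rot[, dab_idx] <- -rot[, dab_idx]
    sc[, dab_idx] <- -sc[, dab_idx]
  }
  structure(list(
    loadings = rot, scores = sc, variance_explained = ve,
    component_tests = tests, dab_component = dab_idx,
    dab = tibble(animal_id = rownames(m), dab = sc[, dab_idx]),
    scaled_matrix = scale(m)
  ), class = "dab_scores")
}

#' @export
print.dab_scores <- function(x, ...) {
  cat(sprintf("<dab_scores> DAB = PC%d (%.0f%% of behavioral variance)\n",
              x$dab_component, 100 * x$variance_explained[x$dab_component]))
  invisible(x)
}

#' @rdname behavior_pca_dab
#' @param x a `dab_scores` object.
#' @param ... unused.
#' @method tidy dab_scores
#' @export
tidy.dab_scores <- function(x, ...) {
  as_tibble(x$loadings, rownames = "behavior") |>
    tidyr::pivot_longer(-"behavior", names_to = "component", values_to = "loading")
}

#' @rdname behavior_pca_dab
#' @method glance dab_scores
#' @export
glance.dab_scores <- function(x, ...) {
  tibble(dab_component = x$dab_component,
         variance_explained = x$variance_explained[x$dab_component],
         p_diet = x$component_tests$p[x$dab_component],
         p_diet_holm = x$component_tests$p_holm[x$dab_component])
}

#' Correlate individual behaviors with the DAB score
#'
#' Pearson correlation of each summary behavior with the DAB composite,
#' two-sided p from the t transform, Holm-adjusted across behaviors.
#' Constant behaviors are returned with `NA` correlation and flagged.
#'
#' @param behaviors a [summarize_focal_observations()] result.
#' @param dab a [behavior_pca_dab()] result (or tibble `animal_id`, `dab`).
#' @return tibble: `behavior`, `kind`, `r`, `p`, `p_holm`, `constant`.
#' @export
dab_behavior_correlations <- function(behaviors, dab) {
  if (inherits(dab, "dab_scores")) dab <- dab$dab
  df <- left_join(as_tibble(behaviors), dab, by = "animal_id")
  if (anyNA(df$dab)) abort("behavior and DAB animals do not align")
  out <- df |>
    group_by(.data$behavior, .data$kind) |>
    summarise(
      constant = sd(.data$value) == 0,
      r = if (sd(.data$value) == 0) NA_real_ else cor(.data$value, .data$dab),
      p = if (sd(.data$value) == 0) NA_real_ else cor.test(.data$value, .data$dab)$p.value,
      .groups = "drop"
    )
  if (any(out$constant)) warn("constant behavior(s): correlation undefined, flagged")
  mutate(out, p_holm = ifelse(is.na(out$p), NA_real_, holm_bonferroni(tidyr::replace_na(out$p, 1))))
}
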