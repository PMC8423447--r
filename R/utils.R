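#' @importFrom rlang %||% abort warn inform .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate arrange filter select bind_rows group_by summarise ungroup desc n left_join
#' @importFrom stats median mad sd var cor cor.test coef lm pt pnorm qnorm quantile
#'   rnorm rbinom rpois rnbinom runif rexp p.adjust fisher.test wilcox.test t.test
#'   phyper qhyper rhyper rmultinom optimize setNames complete.cases prcomp ecdf
#' @importFrom utils head modifyList
NULL

# consistent diet coding used across the package: Western = 1, Mediterranean = 0,
# so positive coefficients mean higher in Western-fed animals
DIET_LEVELS <- c("Mediterranean", "Western")

#' @keywords internal
diet_to_indicator <- function(diet) {
  if (is.numeric(diet)) {
    u <- sort(unique(diet))
    if (!all(u %in% c(0, 1))) abort("numeric diet must be coded 0/1 (1 = Western)")
    return(as.numeric(diet))
  }
  d <- as.character(diet)
  bad <- setdiff(unique(d), DIET_LEVELS)
  if (length(bad) > 0) {
    abort(paste0("unknown diet labels: ", paste(bad, collapse = ", "),
                 " (expected 'Western'/'Mediterranean')"))
  }
  as.numeric(d == "Western")
}

#' @keywords internal
assert_count <- function(x, name, positive = TRUE) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x != round(x) ||
      (positive && x <= 0) || (!positive && x < 0)) {
    abort(sprintf("`%s` must be a %s integer", name, if (positive) "positive" else "non-negative"))
  }
  as.integer(x)
}

#' @keywords internal
assert_fraction <- function(x, name) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must lie in [0, 1]", name))
  }
  as.numeric(x)
}

# child seeds derived by fixed offsets so pipeline stages are reproducible in
# isolation; kept well below .Machine$integer.max
#' @keywords internal
child_seed <- function(seed, k) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(k)
}
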