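# Seeded simulation of labeled multivariate environmental tables.

#' Simulate a grouped environmental table
#'
#' Draws independent Gaussian occurrence records per group around the given
#' group means with a common (pooled) per-variable standard deviation, the
#' structure assumed by the one-way Pillai-trace MANOVA.
#'
#' @param group_means Numeric matrix, groups x variables (row/column names
#'   used when present).
#' @param pooled_sd Positive numeric vector of per-variable standard
#'   deviations (recycled across variables).
#' @param n_per_group Integer vector of records per group (recycled).
#' @param seed Integer seed.
#' @return Tibble with a `group` column followed by the environmental
#'   variables.
#' @export
#' @examples
#' m <- rbind(electricus = c(AMT = 25, AMP = 2200),
#'            voltai     = c(AMT = 26, AMP = 1900))
#' simulate_env_table(m, pooled_sd = c(1, 150), n_per_group = 10, seed = 1)
simulate_env_table <- function(group_means, pooled_sd, n_per_group, seed) {
  group_means <- as.matrix(group_means)
  G <- nrow(group_means)
  V <- ncol(group_means)
  if (G < 1L || V < 1L) abort("`group_means` must have >= 1 row and column")
  pooled_sd <- rep_len(as.numeric(pooled_sd), V)
  if (any(!is.finite(pooled_sd)) || any(pooled_sd <= 0)) {
    abort("`pooled_sd` must be positive")
  }
  n_per_group <- rep_len(
    vapply(rep_len(n_per_group, G), check_count, integer(1), name = "n_per_group"),
    G
  )
  gnames <- rownames(group_means)
  if (is.null(gnames)) gnames <- paste0("group", seq_len(G))
  vnames <- colnames(group_means)
  if (is.null(vnames)) vnames <- paste0("var", seq_len(V))
  with_seed(seed, {
    rows <- lapply(seq_len(G), function(g) {
      n <- n_per_group[g]
      x <- matrix(rnorm(n * V), n, V)
      x <- sweep(x, 2L, pooled_sd, `*`)
      x <- sweep(x, 2L, group_means[g, ], `+`)
      colnames(x) <- vnames
      dplyr::bind_cols(tibble(group = gnames[g]), as_tibble(x))
    })
    dplyr::bind_rows(rows)
  })
}
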