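# One-way Pillai-trace MANOVA for multivariate environmental separation
# among lineages.

#' Pillai-trace MANOVA
#'
#' Tests multivariate separation of group means: Pillai's trace
#' `V = tr(H (H + E)^-1)` from the between-group (H) and within-group (E)
#' cross-product matrices, with the standard F approximation. `V` is bounded
#' by `min(#variables, #groups - 1)`.
#'
#' @param data Data frame with one grouping column and numeric environmental
#'   variables (all other columns). No missing values; at least 2 groups
#'   with 2 records each and more records than variables + groups.
#' @param group Name of the grouping column (default `"group"`).
#' @return Object of class `pillai_manova`; see [glance.pillai_manova()].
#' @export
#' @examples
#' m <- rbind(a = c(x = 0, y = 0), b = c(x = 3, y = 1))
#' tab <- simulate_env_table(m, pooled_sd = 1, n_per_group = 15, seed = 2)
#' pillai_manova(tab)
pillai_manova <- function(data, group = "group") {
  data <- as.data.frame(data)
  if (!group %in% names(data)) {
    abort(sprintf("no grouping column '%s'", group))
  }
  g <- factor(data[[group]])
  Y <- data[, setdiff(names(data), group), drop = FALSE]
  if (!all(vapply(Y, is.numeric, logical(1)))) {
    abort("all non-group columns must be numeric")
  }
  Y <- as.matrix(Y)
  if (anyNA(Y) || anyNA(g)) abort("missing values are not allowed")
  if (nlevels(g) < 2L || any(table(g) < 2L)) {
    abort("need >= 2 groups with >= 2 records each")
  }
  if (nrow(Y) <= ncol(Y) + nlevels(g)) {
    abort("need more records than variables + groups")
  }
  # collinear columns make H + E singular; name them for the caller
  qd <- qr(scale(Y, center = TRUE, scale = FALSE))
  if (qd$rank < ncol(Y)) {
    bad <- colnames(Y)[qd$pivot[(qd$rank + 1L):ncol(Y)]]
    abort(sprintf(
      "singular cross-product matrix; collinear columns: %s",
      paste(bad, collapse = ", ")
    ))
  }
  fit <- manova(Y ~ g)
  st <- summary(fit, test = "Pillai")$stats
  structure(
    list(
      statistic = unname(st[1L, "Pillai"]),
      approx_f = unname(st[1L, "approx F"]),
      df = unname(c(st[1L, "num Df"], st[1L, "den Df"])),
      p_value = unname(st[1L, "Pr(>F)"]),
      n_groups = nlevels(g),
      n_vars = ncol(Y),
      n_obs = nrow(Y),
      variables = colnames(Y),
      group_sizes = as.integer(table(g))
    ),
    class = "pillai_manova"
  )
}

#' @export
print.pillai_manova <- function(x, ...) {
  cat(sprintf(
    "<pillai_manova> %d groups, %d variables, %d records\n  Pillai V = %.4f, F(%g, %g) = %.3f, p = %.3g\n",
    x$n_groups, x$n_vars, x$n_obs, x$statistic, x$df[1L], x$df[2L],
    x$approx_f, x$p_value
  ))
  invisible(x)
}

#' @describeIn pillai_manova One-row summary of the test.
#' @param x A `pillai_manova`.
#' @param ... Unused.
#' @export
glance.pillai_manova <- function(x, ...) {
  tibble(
    pillai = x$statistic,
    statistic = x$approx_f,
    num.df = x$df[1L],
    den.df = x$df[2L],
    p.value = x$p_value,
    n_groups = x$n_groups,
    n_vars = x$n_vars,
    n_obs = x$n_obs
  )
}

#' @describeIn pillai_manova Alias of `glance()` returning the same one-row
#'   tibble.
#' @export
tidy.pillai_manova <- function(x, ...) glance(x)
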