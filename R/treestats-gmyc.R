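# Single-threshold general mixed Yule-coalescent (GMYC) model: a threshold
# time T separates diversification (Yule) branching above T from
# within-species coalescence below T on an ultrametric tree.  Inter-event
# waiting times above T are exponential with rate lambda_y * n^p_y (n =
# extant lineages); below T the total rate is lambda_c * sum_k
# [n_k (n_k - 1)]^p_c over the clusters k defined by the lineages crossing
# T.  Both rates are profiled out analytically; only the two scaling
# exponents are optimized (bounded in [0, 2]).

# internal: parent vector (0 for the root)
parent_vector <- function(tree) {
  n <- length(tree$tip.label) + tree$Nnode
  par <- integer(n)
  par[tree$edge[, 2L]] <- tree$edge[, 1L]
  par
}

# internal: profiled log-likelihood of the single-class (Yule) process as a
# function of the scaling exponent p.  `x` segment durations, `w` per-segment
# rate bases, `ev` rate bases at the events.
profile_part <- function(x, w, ev) {
  m <- length(ev)
  if (m == 0L) {
    return(list(loglik = function(p) 0, m = 0L, lambda = function(p) 0))
  }
  Clog <- sum(log(ev))
  list(
    loglik = function(p) {
      S <- sum(x * w^p)
      m * (log(m) - log(S) - 1) + p * Clog
    },
    m = m,
    lambda = function(p) m / sum(x * w^p)
  )
}

# internal: profiled log-likelihood of the coalescent class.  The waiting
# times form one merged stream whose rate in segment i is
# lambda * sum_k [n_ki (n_ki - 1)]^p over clusters k (total rate: events are
# unlabeled, which keeps the threshold model comparable with the
# single-process null).  `x` segment durations, `V` segments-by-clusters
# matrix of n (n - 1) values, `ev_seg` the segment index whose waiting time
# each event terminates.
profile_part_coal <- function(x, V, ev_seg) {
  m <- length(ev_seg)
  if (m == 0L) {
    return(list(loglik = function(p) 0, m = 0L, lambda = function(p) 0))
  }
  mask <- V > 0
  rate_base <- function(p) {
    W <- matrix(0, nrow(V), ncol(V))
    W[mask] <- V[mask]^p
    rowSums(W)
  }
  list(
    loglik = function(p) {
      R <- rate_base(p)
      m * (log(m) - log(sum(x * R)) - 1) + sum(log(R[ev_seg]))
    },
    m = m,
    lambda = function(p) m / sum(x * rate_base(p))
  )
}

# internal: maximize a profiled part over p in [0, 2] (coarse grid plus
# local refinement; deterministic)
maximize_part <- function(part) {
  if (part$m == 0L) return(list(p = NA_real_, value = 0, lambda = 0))
  grid <- seq(0, 2, by = 0.125)
  vals <- vapply(grid, part$loglik, numeric(1))
  i <- which.max(vals)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  o <- optimize(part$loglik, c(lo, hi), maximum = TRUE, tol = 1e-10)
  if (o$objective < vals[i]) o <- list(maximum = grid[i], objective = vals[i])
  list(p = o$maximum, value = o$objective, lambda = part$lambda(o$maximum))
}

# internal: per-threshold interval data.  Every internal node is an event
# exactly once, so all candidate thresholds see the same n_tip - 1 events.
# Yule events (above T) take their rate base from the lineage count on the
# deeper side (the interval the forward-time wait occupies; the root enters
# as a rate-only factor); coalescent events (below T) from the shallower
# side (the interval the backward-time wait occupies).
gmyc_threshold_data <- function(tree, heights, par, T) {
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  root <- n_tip + 1L
  internals <- (n_tip + 1L):n_all
  h_int <- heights[internals]
  root_h <- heights[root]

  # cluster of every node below T: itself if its parent branch crosses T
  # (or it is the root, when T lies above the root), else its parent's
  # cluster; resolved in decreasing height order so parents come first
  cluster <- integer(n_all)
  ord <- order(heights, decreasing = TRUE)
  for (v in ord) {
    if (heights[v] >= T) next
    p <- par[v]
    cluster[v] <- if (p == 0L || heights[p] > T) v else cluster[p]
  }
  if (T > root_h) cluster[root] <- root
  tip_cluster <- cluster[seq_len(n_tip)]
  k <- length(unique(tip_cluster))

  # --- Yule side: segments from the root down to T
  x_y <- numeric(0)
  w_y <- numeric(0)
  ev_y <- numeric(0)
  if (T < root_h) {
    bnd <- sort(unique(c(root_h, h_int[h_int > T], T)), decreasing = TRUE)
    a <- bnd[-length(bnd)]
    b <- bnd[-1L]
    x_y <- a - b
    w_y <- vapply(a, function(top) 1 + sum(h_int >= top), numeric(1))
    keep <- x_y > 0
    x_y <- x_y[keep]
    w_y <- w_y[keep]
    # every node above T is a Yule event, including the root (which enters
    # as a rate-only factor: there is no interval above it)
    he <- heights[internals[h_int > T]]
    ev_y <- vapply(he, function(h) 1 + sum(h_int > h), numeric(1))
  }

  # --- Coalescent side: merged waiting-time stream below T with total rate
  # summed over clusters
  top0 <- min(T, root_h)
  hh_all <- h_int[h_int < T]
  coal <- list(loglik = function(p) 0, m = 0L, lambda = function(p) 0)
  cl_int <- cluster[internals]
  cl_ids <- unique(cl_int[cl_int != 0L])
  if (length(hh_all) > 0L && length(cl_ids) > 0L) {
    bnd <- sort(unique(c(top0, hh_all, 0)), decreasing = TRUE)
    a <- bnd[-length(bnd)]
    b <- bnd[-1L]
    x_c <- a - b
    V <- matrix(0, length(a), length(cl_ids))
    for (ci in seq_along(cl_ids)) {
      hs <- h_int[cl_int == cl_ids[ci]]
      nk <- 1 + vapply(a, function(top) sum(hs >= top), numeric(1))
      V[, ci] <- nk * (nk - 1)
    }
    ev_seg <- match(hh_all, a)
    coal <- profile_part_coal(x_c, V, ev_seg)
  }

  list(
    yule = profile_part(x_y, w_y, ev_y),
    coal = coal,
    k = k,
    tip_cluster = tip_cluster
  )
}

#' Fit the single-threshold GMYC model
#'
#' Candidate thresholds are the midpoints between consecutive distinct
#' internal node heights (plus one candidate below all nodes and one above
#' the root, the latter reducing the model to the null single-process
#' coalescent so that the fitted likelihood always dominates the null). The
#' profile likelihood is maximized over candidates; the likelihood-ratio
#' statistic `2 (logL_fit - logL_null)` is referred to a chi-square
#' distribution with 3 degrees of freedom (threshold, second rate, second
#' exponent).
#'
#' The reported `clusters`/`n_clusters` describe the supported partition:
#' the maximum-likelihood threshold partition when the likelihood-ratio test
#' rejects the single-process null at 0.05, and a single cluster otherwise.
#' The unconditional maximum-likelihood partition is kept in `ml_clusters`.
#'
#' @param tree A rooted, ultrametric [ape::phylo] tree with >= 4 tips.
#' @param alpha Significance level used to decide whether the threshold
#'   partition is supported (default 0.05).
#' @return An object of class `gmyc_fit`; see [tidy.gmyc_fit()] and
#'   [glance.gmyc_fit()].
#' @export
#' @examples
#' tr <- simulate_tree(3, c(5, 5, 5), 5, 0.4, seed = 7)
#' fit <- gmyc_fit(tr)
#' glance(fit)
gmyc_fit <- function(tree, alpha = 0.05) {
  stopifnot(inherits(tree, "phylo"))
  n_tip <- length(tree$tip.label)
  if (n_tip < 4L) abort("GMYC needs at least 4 tips")
  heights <- node_heights(tree) # errors if not ultrametric
  par <- parent_vector(tree)
  root_h <- heights[n_tip + 1L]
  h_int <- heights[(n_tip + 1L):(n_tip + tree$Nnode)]
  hs <- sort(unique(h_int), decreasing = TRUE)

  null_fit <- gmyc_null_loglik(tree, detail = TRUE)

  if (length(hs) == 1L) {
    # degenerate: all internal nodes at one height; only the null applies
    one <- tibble(tip = tree$tip.label, cluster = 1L)
    return(structure(
      list(
        threshold = root_h, loglik = null_fit$loglik,
        null_loglik = null_fit$loglik, lrt = 0, df = 3L, p_value = 1,
        supported = FALSE, n_clusters = 1L, ml_n_clusters = 1L,
        clusters = one, ml_clusters = one,
        params = c(
          lambda_yule = NA_real_, p_yule = NA_real_,
          lambda_coal = null_fit$lambda, p_coal = null_fit$p
        ),
        null_params = c(lambda = null_fit$lambda, p = null_fit$p),
        profile = tibble(threshold = root_h, loglik = null_fit$loglik, k = 1),
        n_tip = n_tip, root_height = root_h
      ),
      class = "gmyc_fit"
    ))
  }
  cands <- root_h * 1.05
  if (length(hs) > 1L) cands <- c(cands, (hs[-1L] + hs[-length(hs)]) / 2)
  cands <- c(cands, min(hs) / 2)

  prof <- lapply(cands, function(T) {
    dat <- gmyc_threshold_data(tree, heights, par, T)
    fy <- maximize_part(dat$yule)
    fc <- maximize_part(dat$coal)
    list(
      T = T, loglik = fy$value + fc$value, k = dat$k,
      p_yule = fy$p, lambda_yule = fy$lambda,
      p_coal = fc$p, lambda_coal = fc$lambda,
      tip_cluster = dat$tip_cluster
    )
  })
  ll <- vapply(prof, `[[`, numeric(1), "loglik")
  best <- prof[[which.max(ll)]]
  loglik <- max(best$loglik, null_fit$loglik)
  lrt <- max(0, 2 * (loglik - null_fit$loglik))
  p_value <- pchisq(lrt, df = 3, lower.tail = FALSE)

  ml_clusters <- tibble(
    tip = tree$tip.label,
    cluster = match(best$tip_cluster, unique(best$tip_cluster))
  )
  supported <- p_value < alpha
  clusters <- if (supported) ml_clusters else tibble(
    tip = tree$tip.label, cluster = 1L
  )
  structure(
    list(
      threshold = best$T,
      loglik = loglik,
      null_loglik = null_fit$loglik,
      lrt = lrt,
      df = 3L,
      p_value = p_value,
      supported = supported,
      n_clusters = max(clusters$cluster),
      ml_n_clusters = best$k,
      clusters = clusters,
      ml_clusters = ml_clusters,
      params = c(
        lambda_yule = best$lambda_yule, p_yule = best$p_yule,
        lambda_coal = best$lambda_coal, p_coal = best$p_coal
      ),
      null_params = c(lambda = null_fit$lambda, p = null_fit$p),
      profile = tibble(
        threshold = vapply(prof, `[[`, numeric(1), "T"),
        loglik = ll,
        k = vapply(prof, `[[`, numeric(1), "k")
      ),
      n_tip = n_tip,
      root_height = root_h
    ),
    class = "gmyc_fit"
  )
}

#' Null (single-process) GMYC log-likelihood
#'
#' Likelihood of a single coalescent-class branching process (one rate, one
#' exponent in [0, 2]) over all waiting intervals of the tree; the null
#' model of the GMYC likelihood-ratio test.
#'
#' @param tree A rooted ultrametric [ape::phylo] tree.
#' @param detail Return the fitted rate and exponent as well.
#' @return The maximized log-likelihood (or a list when `detail = TRUE`).
#' @export
gmyc_null_loglik <- function(tree, detail = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  n_tip <- length(tree$tip.label)
  heights <- node_heights(tree)
  h_int <- heights[(n_tip + 1L):(n_tip + tree$Nnode)]
  root_h <- max(h_int)
  bnd <- sort(unique(c(h_int, 0)), decreasing = TRUE)
  a <- bnd[-length(bnd)]
  b <- bnd[-1L]
  x <- a - b
  nlin <- vapply(a, function(top) 1 + sum(h_int >= top), numeric(1))
  w <- nlin * (nlin - 1)
  keep <- x > 0 & w > 0
  # events: every internal node including the root (the standard coalescent
  # likelihood); rate base = lineage count on the shallower side
  ev_h <- sort(h_int, decreasing = TRUE)
  nk <- 1 + vapply(ev_h, function(he) sum(h_int >= he), numeric(1))
  ev <- nk * (nk - 1)
  part <- profile_part(x[keep], w[keep], ev)
  fit <- maximize_part(part)
  if (detail) {
    list(loglik = fit$value, lambda = fit$lambda, p = fit$p)
  } else {
    fit$value
  }
}

#' @export
print.gmyc_fit <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<gmyc_fit> %d tips; threshold %.4g (root %.4g)\n",
      "  logL = %.4f, null logL = %.4f, LRT = %.3f (df 3), p = %.3g\n",
      "  clusters: %d%s\n"
    ),
    x$n_tip, x$threshold, x$root_height, x$loglik, x$null_loglik,
    x$lrt, x$p_value, x$n_clusters,
    if (x$supported) "" else sprintf(" (ML partition %d, not supported)", x$ml_n_clusters)
  ))
  invisible(x)
}

#' @describeIn gmyc_fit Tidy cluster membership (tip, cluster).
#' @param x A `gmyc_fit`.
#' @param ... Unused.
#' @export
tidy.gmyc_fit <- function(x, ...) x$clusters

#' @describeIn gmyc_fit One-row model summary.
#' @export
glance.gmyc_fit <- function(x, ...) {
  tibble(
    n_tip = x$n_tip,
    threshold = x$threshold,
    logLik = x$loglik,
    null_logLik = x$null_loglik,
    statistic = x$lrt,
    df = x$df,
    p.value = x$p_value,
    n_clusters = x$n_clusters,
    ml_n_clusters = x$ml_n_clusters
  )
}

#' Profile likelihood of a GMYC fit
#'
#' @param object A `gmyc_fit`.
#' @param ... Unused.
#' @return A ggplot of profile log-likelihood against candidate threshold,
#'   with the chosen threshold marked.
#' @export
autoplot.gmyc_fit <- function(object, ...) {
  ggplot2::ggplot(object$profile, ggplot2::aes(x = .data$threshold, y = .data$loglik)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$k), alpha = 0.6) +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = 2) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(
      x = "candidate threshold (time before present)",
      y = "profile log-likelihood", size = "clusters",
      title = "GMYC profile likelihood"
    )
}
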