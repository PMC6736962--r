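# Distance-based lineage discovery (barcode-gap partitioning) and the
# molecular-diagnosis screen for fixed, unique nucleotide states.

# internal: find the lower edge of the first significant barcode gap in a
# vector of pairwise distances, given a prior intraspecific limit `prior`.
# A gap between consecutive ranked distances is significant when it ends
# above the prior, is wider than `relative_gap` times the local slope of the
# ranked-distance curve (mean spacing over the preceding `window` ranks), and
# is wider than the prior itself (so that spacing noise below the prior scale
# never splits a cluster). Returns NA when no gap qualifies.
find_gap_edge <- function(dists, prior, relative_gap, window = 10L) {
  v <- sort(dists[is.finite(dists)])
  if (length(v) < 2L) return(NA_real_)
  gaps <- diff(v)
  overall <- mean(gaps[gaps > 0])
  if (!is.finite(overall) || overall == 0) return(NA_real_)
  for (i in seq_along(gaps)) {
    if (v[i + 1L] <= prior) next
    lo <- max(1L, i - window)
    prev <- gaps[seq(lo, max(lo, i - 1L))]
    slope <- if (i == 1L || all(prev == 0)) overall else mean(prev)
    if (gaps[i] > relative_gap * slope && gaps[i] > prior) {
      return(v[i])
    }
  }
  NA_real_
}

# internal: connected components of the graph linking pairs with distance
# <= edge (saturated/NA pairs count as above any threshold)
components_below <- function(D, edge) {
  n <- nrow(D)
  adj <- !is.na(D) & D <= edge
  diag(adj) <- TRUE
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      u <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(adj[u, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# internal: recursive gap partition at one prior value
partition_at_prior <- function(D, prior, relative_gap, depth = 0L,
                               max_depth = 10L) {
  n <- nrow(D)
  if (n < 2L || depth >= max_depth) {
    return(list(comp = rep(1L, n), depth = depth, edge = NA_real_))
  }
  dists <- D[upper.tri(D)]
  edge <- find_gap_edge(dists, prior, relative_gap)
  if (is.na(edge) && anyNA(dists) && any(is.finite(dists))) {
    # saturated pairs sit above any threshold: they imply an infinite gap
    # beyond the largest finite distance
    edge <- max(dists[is.finite(dists)])
  }
  if (is.na(edge)) {
    return(list(comp = rep(1L, n), depth = depth, edge = NA_real_))
  }
  comp <- components_below(D, edge)
  out <- integer(n)
  nxt <- 0L
  max_d <- depth
  for (k in sort(unique(comp))) {
    sel <- comp == k
    if (sum(sel) >= 3L) {
      subres <- partition_at_prior(
        D[sel, sel, drop = FALSE], prior, relative_gap, depth + 1L, max_depth
      )
      out[sel] <- nxt + subres$comp
      nxt <- nxt + max(subres$comp)
      max_d <- max(max_d, subres$depth)
    } else {
      nxt <- nxt + 1L
      out[sel] <- nxt
    }
  }
  list(comp = out, depth = max_d, edge = edge)
}

# internal: canonical cluster labels (first-occurrence order, 1-based)
canonical_partition <- function(comp) {
  match(comp, unique(comp))
}

#' Barcode-gap partition of individuals
#'
#' Re-implementation of automatic barcode-gap discovery in simplified,
#' reproducible form. For each prior intraspecific limit `P` on a log grid,
#' the ranked pairwise distances are scanned for the first significant gap
#' beyond `P` (wider than `relative_gap` times the local slope of the
#' ranked-distance curve and wider than `P`); individuals are partitioned
#' into connected components of the graph linking pairs below the gap's lower
#' edge, and the scan recurses within components until no further gap is
#' significant. The partition stable across the widest contiguous sub-range
#' of the prior grid is returned as the primary partition.
#'
#' @param dm A `k2p_dist` from [distance_matrix()], or a symmetric numeric
#'   distance matrix.
#' @param p_min,p_max Prior intraspecific divergence range (substitutions per
#'   site), scanned on a log grid.
#' @param relative_gap Gap width multiplier relative to the local ranked
#'   slope (customary value 1.5).
#' @param steps Number of prior values on the log grid.
#' @return An object of class `eel_partition`: a tibble with columns
#'   `individual` and `cluster` (cluster IDs contiguous from 1), with the
#'   selected prior, threshold edge and recursion depth as attributes.
#' @export
barcode_gap_partition <- function(dm, p_min = 0.001, p_max = 0.1,
                                  relative_gap = 1.5, steps = 20L) {
  if (inherits(dm, "k2p_dist")) {
    D <- dm$d
    D[dm$saturated] <- NA_real_
    labels <- dm$labels
  } else {
    D <- as.matrix(dm)
    labels <- rownames(D)
    if (is.null(labels)) labels <- paste0("seq", seq_len(nrow(D)))
  }
  if (!(p_min >= 0 && p_min < p_max)) abort("need 0 <= p_min < p_max")
  steps <- check_count(steps, "steps", min = 1L)
  lo <- max(p_min, 1e-8)
  grid <- exp(seq(log(lo), log(p_max), length.out = steps))
  fits <- lapply(grid, function(P) {
    partition_at_prior(D, P, relative_gap)
  })
  keys <- vapply(
    fits, function(f) paste(canonical_partition(f$comp), collapse = ","),
    character(1)
  )
  # longest run of consecutive priors with an identical partition
  r <- rle(keys)
  best <- which.max(r$lengths)
  pick <- sum(r$lengths[seq_len(best)]) # last index of the winning run
  f <- fits[[pick]]
  comp <- canonical_partition(f$comp)
  out <- tibble(individual = labels, cluster = comp)
  structure(
    out,
    prior = grid[pick],
    prior_range = range(grid[keys == keys[pick]]),
    threshold = f$edge,
    depth = f$depth,
    n_clusters = max(comp),
    class = c("eel_partition", class(out))
  )
}

#' @export
print.eel_partition <- function(x, ...) {
  cat(sprintf(
    "<eel_partition> %d individuals in %d clusters (threshold %.4g, prior %.4g)\n",
    nrow(x), attr(x, "n_clusters"),
    attr(x, "threshold") %||% NA_real_, attr(x, "prior") %||% NA_real_
  ))
  NextMethod()
}

#' Number of clusters in a partition
#' @param x An `eel_partition`.
#' @return Integer cluster count.
#' @export
n_clusters <- function(x) {
  if (inherits(x, "eel_partition")) return(attr(x, "n_clusters"))
  length(unique(x$cluster))
}

#' Diagnostic nucleotide sites of a lineage
#'
#' Screens every alignment column for states fixed in the focal lineage and
#' absent from all other ingroup individuals. Positions are reported 1-based
#' on the analyzed fragment after dropping columns where only the outgroup
#' has a residue; the outgroup anchors coordinates but never vetoes
#' uniqueness (diagnosability is assessed among congeners).
#'
#' @param aln A `labeled_alignment` (outgroup rows tagged `"outgroup"`).
#' @param focal Focal lineage tag.
#' @return Tibble of class `diagnostic_sites` with columns `lineage`,
#'   `position`, `state`.
#' @export
diagnostic_sites <- function(aln, focal) {
  stopifnot(inherits(aln, "labeled_alignment"))
  tags <- attr(aln, "lineage")
  if (!focal %in% tags) abort(sprintf("focal lineage '%s' absent from alignment", focal))
  m <- toupper(unclass(aln))
  ingroup <- tags != "outgroup"
  # fragment columns: at least one ingroup residue
  frag_cols <- which(colSums(matrix(m[ingroup, ] %in% NUC, nrow = sum(ingroup))) > 0L)
  focal_rows <- tags == focal
  other_rows <- ingroup & !focal_rows
  res <- list()
  pos <- 0L
  for (col in frag_cols) {
    pos <- pos + 1L
    fs <- unname(m[focal_rows, col])
    if (any(!fs %in% NUC)) next # ambiguity/gap in focal lineage: ineligible
    st <- fs[1L]
    if (!all(fs == st)) next
    if (any(m[other_rows, col] == st)) next
    res[[length(res) + 1L]] <- tibble(lineage = focal, position = pos, state = st)
  }
  out <- if (length(res)) dplyr::bind_rows(res) else {
    tibble(lineage = character(), position = integer(), state = character())
  }
  class(out) <- c("diagnostic_sites", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
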