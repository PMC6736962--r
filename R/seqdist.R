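# Kimura two-parameter pairwise distances and within/between-lineage
# divergence summaries (the barcoding arithmetic of the delimitation
# pipeline).

# internal: K2P closed form from transition/transversion proportions.
# Returns NA where the logarithm arguments are non-positive (saturation).
k2p_core <- function(P, Q) {
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  d <- ifelse(a1 > 0 & a2 > 0, -0.5 * log(pmax(a1, .Machine$double.xmin)) -
    0.25 * log(pmax(a2, .Machine$double.xmin)), NA_real_)
  d
}

# internal: encode sequences as integers 1..4 (A,C,G,T), NA otherwise
encode_nuc <- function(x) {
  if (is.character(x) && length(x) == 1L) x <- strsplit(toupper(x), "")[[1L]]
  if (is.character(x)) x <- match(toupper(x), NUC)
  x
}

#' Kimura two-parameter distance between two sequences
#'
#' Computes `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)` where `P` and `Q`
#' are the transition and transversion proportions over compared sites.
#' Columns where either sequence carries a gap or a non-ACGT symbol are
#' excluded (pairwise deletion).
#'
#' @param seq_a,seq_b Nucleotide sequences of equal length, as single strings
#'   or character vectors of residues.
#' @return Tibble with columns `distance`, `sites`, `P`, `Q`.
#' @export
#' @examples
#' k2p_distance(strrep("A", 10), strrep("A", 10))
k2p_distance <- function(seq_a, seq_b) {
  a <- encode_nuc(seq_a)
  b <- encode_nuc(seq_b)
  if (length(a) != length(b)) abort("sequences must have equal length")
  ok <- !is.na(a) & !is.na(b)
  n <- sum(ok)
  if (n == 0L) abort("no comparable sites (all gapped or ambiguous)")
  a <- a[ok]
  b <- b[ok]
  diffs <- a != b
  ts <- sum(diffs & TS_PARTNER[a] == b)
  tv <- sum(diffs) - ts
  P <- ts / n
  Q <- tv / n
  d <- k2p_core(P, Q)
  if (is.na(d)) {
    abort(
      sprintf("K2P distance undefined (saturation): P = %.3f, Q = %.3f", P, Q),
      class = "eeldelim_saturation"
    )
  }
  tibble(distance = d, sites = n, P = P, Q = Q)
}

#' All pairwise K2P distances of an alignment
#'
#' Saturated pairs (where the K2P logarithms are undefined) are flagged, not
#' dropped, and carry `NA` distances.
#'
#' @param aln A `labeled_alignment` or a character matrix of aligned
#'   residues with row names.
#' @return An object of class `k2p_dist` holding the symmetric distance
#'   matrix, per-pair compared-site counts and saturation flags; convert with
#'   [tidy()] for a long tibble.
#' @export
distance_matrix <- function(aln) {
  m <- unclass(aln)
  if (!is.matrix(m) || nrow(m) < 2L) abort("need an alignment of >= 2 sequences")
  labels <- rownames(m)
  if (is.null(labels)) labels <- paste0("seq", seq_len(nrow(m)))
  enc <- matrix(match(toupper(m), NUC), nrow = nrow(m))
  n <- nrow(enc)
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  S <- matrix(ncol(enc), n, n, dimnames = list(labels, labels))
  SAT <- matrix(FALSE, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    ai <- enc[i, ]
    for (j in (i + 1L):n) {
      bj <- enc[j, ]
      ok <- !is.na(ai) & !is.na(bj)
      ns <- sum(ok)
      if (ns == 0L) {
        D[i, j] <- D[j, i] <- NA_real_
        S[i, j] <- S[j, i] <- 0L
        SAT[i, j] <- SAT[j, i] <- TRUE
        next
      }
      a <- ai[ok]
      b <- bj[ok]
      diffs <- a != b
      ts <- sum(diffs & TS_PARTNER[a] == b)
      tv <- sum(diffs) - ts
      d <- k2p_core(ts / ns, tv / ns)
      D[i, j] <- D[j, i] <- d
      S[i, j] <- S[j, i] <- ns
      if (is.na(d)) SAT[i, j] <- SAT[j, i] <- TRUE
    }
  }
  lineage <- attr(aln, "lineage")
  structure(
    list(labels = labels, d = D, sites = S, saturated = SAT, lineage = lineage),
    class = "k2p_dist"
  )
}

#' @export
print.k2p_dist <- function(x, ...) {
  n <- length(x$labels)
  v <- x$d[upper.tri(x$d)]
  cat(sprintf(
    "<k2p_dist> %d sequences, %d pairs; distance range %.4g-%.4g; %d saturated\n",
    n, length(v), min(v, na.rm = TRUE), max(v, na.rm = TRUE),
    sum(x$saturated[upper.tri(x$saturated)])
  ))
  invisible(x)
}

#' @export
tidy.k2p_dist <- function(x, ...) {
  n <- length(x$labels)
  idx <- which(upper.tri(x$d), arr.ind = TRUE)
  out <- tibble(
    seq_a = x$labels[idx[, 1L]],
    seq_b = x$labels[idx[, 2L]],
    distance = x$d[idx],
    sites = x$sites[idx],
    saturated = x$saturated[idx]
  )
  if (!is.null(x$lineage)) {
    out$lineage_a <- unname(x$lineage[out$seq_a])
    out$lineage_b <- unname(x$lineage[out$seq_b])
  }
  out
}

#' Within- and between-lineage mean K2P divergences
#'
#' Arithmetic means over the relevant pair sets, reported both in
#' substitutions/site and percent. A lineage with a single member has an
#' undefined within-lineage mean (`NA`, not zero); saturated pairs are
#' excluded from the means and counted in `n_saturated`.
#'
#' @param dm A `k2p_dist` from [distance_matrix()].
#' @param labels Individual-to-lineage map: a named character vector, or a
#'   data frame with columns `individual` and `lineage`. Defaults to the
#'   lineage tags carried by the alignment. Every matrix label must be
#'   mapped.
#' @return Tibble with columns `type` (within/between), `lineage_a`,
#'   `lineage_b`, `mean_dist`, `percent`, `n_pairs`, `n_saturated`.
#' @export
group_divergences <- function(dm, labels = NULL) {
  stopifnot(inherits(dm, "k2p_dist"))
  if (is.null(labels)) labels <- dm$lineage
  if (is.null(labels)) abort("no lineage labels available; supply `labels`")
  if (is.data.frame(labels)) {
    labels <- setNames(labels$lineage, labels$individual)
  }
  if (!all(dm$labels %in% names(labels))) {
    abort("every distance-matrix label must be mapped to a lineage")
  }
  g <- unname(labels[dm$labels])
  lineages <- unique(g)
  rows <- list()
  pair_mean <- function(sel_a, sel_b, within) {
    dsub <- dm$d[sel_a, sel_b, drop = FALSE]
    ssub <- dm$saturated[sel_a, sel_b, drop = FALSE]
    if (within) {
      v <- dsub[upper.tri(dsub)]
      sat <- ssub[upper.tri(ssub)]
    } else {
      v <- as.vector(dsub)
      sat <- as.vector(ssub)
    }
    list(
      mean = if (length(v) == 0L || all(sat)) NA_real_ else mean(v[!sat]),
      n_pairs = length(v), n_sat = sum(sat)
    )
  }
  for (ln in lineages) {
    sel <- g == ln
    if (sum(sel) < 2L) {
      rows[[length(rows) + 1L]] <- tibble(
        type = "within", lineage_a = ln, lineage_b = ln,
        mean_dist = NA_real_, n_pairs = 0L, n_saturated = 0L
      )
    } else {
      pm <- pair_mean(sel, sel, within = TRUE)
      rows[[length(rows) + 1L]] <- tibble(
        type = "within", lineage_a = ln, lineage_b = ln,
        mean_dist = pm$mean, n_pairs = pm$n_pairs, n_saturated = pm$n_sat
      )
    }
  }
  if (length(lineages) > 1L) {
    for (i in seq_len(length(lineages) - 1L)) {
      for (j in (i + 1L):length(lineages)) {
        pm <- pair_mean(g == lineages[i], g == lineages[j], within = FALSE)
        rows[[length(rows) + 1L]] <- tibble(
          type = "between", lineage_a = lineages[i], lineage_b = lineages[j],
          mean_dist = pm$mean, n_pairs = pm$n_pairs, n_saturated = pm$n_sat
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  out$percent <- 100 * out$mean_dist
  out[, c(
    "type", "lineage_a", "lineage_b", "mean_dist", "percent",
    "n_pairs", "n_saturated"
  )]
}

#' Write a distance matrix
#'
#' @param dm A `k2p_dist`.
#' @param path Output file.
#' @param format `"csv"` for a square CSV matrix or `"lower"` for
#'   lower-triangular text.
#' @return `path`, invisibly.
#' @export
write_distances <- function(dm, path, format = c("csv", "lower")) {
  stopifnot(inherits(dm, "k2p_dist"))
  format <- match.arg(format)
  if (format == "csv") {
    write.csv(dm$d, path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_along(dm$labels)) {
      vals <- if (i == 1L) "" else {
        paste(sprintf("%.6f", dm$d[i, seq_len(i - 1L)]), collapse = "\t")
      }
      writeLines(paste(dm$labels[i], vals, sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Histogram of pairwise distances
#'
#' Shows the pooled pairwise-distance distribution, split into within- and
#' between-lineage pairs when lineage tags are available; the barcode gap is
#' the empty interval separating the two modes.
#'
#' @param object A `k2p_dist`.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.k2p_dist <- function(object, bins = 40, ...) {
  df <- tidy(object)
  df <- df[!df$saturated, ]
  if (!is.null(object$lineage)) {
    df$pair_type <- ifelse(df$lineage_a == df$lineage_b, "within", "between")
    ggplot2::ggplot(df, ggplot2::aes(x = .data$distance, fill = .data$pair_type)) +
      ggplot2::geom_histogram(bins = bins, position = "identity", alpha = 0.7) +
      ggplot2::labs(
        x = "K2P distance (subs/site)", y = "pairs", fill = NULL,
        title = "Pairwise distance distribution"
      )
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$distance)) +
      ggplot2::geom_histogram(bins = bins) +
      ggplot2::labs(x = "K2P distance (subs/site)", y = "pairs")
  }
}
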