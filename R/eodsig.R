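# Electric organ discharge waveform pipeline: conditioning to a common
# sampling rate and 256-sample peak-centered window, duration at a 1%
# amplitude threshold, full-depth periodized Symmlet-4 discrete wavelet
# features, pairwise-ANOVA feature selection, single-linkage clustering and
# Mahalanobis D2 between species centroids.

# Symmlet-4 (4 vanishing moments) orthogonal analysis filters
SYM4_LO <- c(
  -0.07576571478927333, -0.02963552764599851, 0.49761866763201545,
  0.80373875180591614, 0.29785779560527736, -0.09921954357684722,
  -0.01260396726203783, 0.03222310060404270
)
SYM4_HI <- c(
  -0.03222310060404270, -0.01260396726203783, 0.09921954357684722,
  0.29785779560527736, -0.80373875180591614, 0.49761866763201545,
  0.02963552764599851, -0.07576571478927333
)

# internal: one periodized analysis step; x of even length N ->
# list(approx, detail) of length N/2.  Convolution alignment:
# a[k] = sum_m h[m] x[(2k + 4 - m) mod N] in 0-based indexing.
dwt_step <- function(x) {
  N <- length(x)
  half <- N / 2L
  a <- numeric(half)
  d <- numeric(half)
  for (k in seq_len(half)) {
    idx <- ((2L * k + 3L - seq_len(8L)) %% N) + 1L
    xs <- x[idx]
    a[k] <- sum(SYM4_LO * xs)
    d[k] <- sum(SYM4_HI * xs)
  }
  list(approx = a, detail = d)
}

# internal: inverse periodized step (transpose of the orthonormal analysis;
# indices can repeat when N < filter length, so accumulate per tap)
idwt_step <- function(a, d) {
  half <- length(a)
  N <- 2L * half
  x <- numeric(N)
  for (k in seq_len(half)) {
    idx <- ((2L * k + 3L - seq_len(8L)) %% N) + 1L
    for (m in seq_len(8L)) {
      x[idx[m]] <- x[idx[m]] + a[k] * SYM4_LO[m] + d[k] * SYM4_HI[m]
    }
  }
  x
}

#' Full-depth Symmlet-4 discrete wavelet transform
#'
#' Orthonormal periodized DWT of a dyadic-length signal down to a single
#' scaling coefficient. For a 256-sample input this yields 8 detail scales:
#' one scaling (approximation) coefficient followed by detail coefficients
#' ordered coarse to fine (`d8` ... `d1`), 256 coefficients in total. The
#' transform is energy preserving (Parseval) and exactly invertible with
#' [idwt_sym4()].
#'
#' @param x Numeric vector whose length is a power of two (a
#'   `conditioned_eod` is accepted), length >= 8.
#' @return Named numeric vector of coefficients (`a<J>`, then `d<J>_<i>`
#'   down to `d1_<i>`).
#' @export
#' @examples
#' co <- dwt_sym4(sin(seq_len(256) / 10))
#' sum(co^2) - sum(sin(seq_len(256) / 10)^2) # ~ 0
dwt_sym4 <- function(x) {
  if (inherits(x, "conditioned_eod")) x <- x$samples
  N <- length(x)
  if (N < 8L || bitwAnd(N, N - 1L) != 0L) {
    abort("input length must be a power of two, >= 8")
  }
  J <- as.integer(log2(N))
  details <- vector("list", J)
  cur <- x
  for (lev in seq_len(J)) {
    st <- dwt_step(cur)
    details[[lev]] <- st$detail
    cur <- st$approx
  }
  out <- c(cur, unlist(rev(details)))
  nm <- paste0("a", J)
  for (lev in rev(seq_len(J))) {
    nm <- c(nm, paste0("d", lev, "_", seq_len(N / 2^lev)))
  }
  names(out) <- nm
  out
}

#' Inverse of [dwt_sym4()]
#'
#' @param coefs Coefficient vector as produced by [dwt_sym4()].
#' @return Reconstructed signal.
#' @export
idwt_sym4 <- function(coefs) {
  N <- length(coefs)
  if (N < 8L || bitwAnd(N, N - 1L) != 0L) {
    abort("coefficient length must be a power of two, >= 8")
  }
  J <- as.integer(log2(N))
  cur <- coefs[1L]
  pos <- 2L
  for (lev in rev(seq_len(J))) {
    nd <- N / 2^lev
    d <- coefs[pos:(pos + nd - 1L)]
    cur <- idwt_step(cur, d)
    pos <- pos + nd
  }
  unname(cur)
}

#' Condition an EOD recording
#'
#' Band-limited resampling to a common rate, extraction of a fixed-length
#' window with the positive peak at index 129 (zero-padded near edges), and
#' normalization to unit root-mean-square amplitude. Conditioned waveforms
#' from different individuals and recording rigs are directly comparable.
#'
#' @param rec An [eod_recording()] (head-positive pulse: global extremum
#'   positive).
#' @param target_rate Common sampling rate in Hz (default 96000).
#' @param window Window length in samples (default 256; must be even).
#' @param flip Set TRUE to flip a recording whose polarity is inverted;
#'   otherwise a negative-peaked signal is an error.
#' @return An object of class `conditioned_eod` with unit-RMS `samples` of
#'   length `window` and the peak at `window/2 + 1`.
#' @export
condition_eod <- function(rec, target_rate = 96000, window = 256L,
                          flip = FALSE) {
  stopifnot(inherits(rec, "eod_recording"))
  window <- check_count(window, "window", min = 8L)
  if (window %% 2L != 0L) abort("`window` must be even")
  x <- rec$samples
  if (all(x == 0)) abort("all-zero signal cannot be conditioned")
  if (max(x) < -min(x)) {
    if (!flip) {
      abort("negative-peaked signal; pass flip = TRUE if the polarity is inverted")
    }
    x <- -x
  }
  if (rec$rate != target_rate) {
    x <- fft_resample(x, round(length(x) * target_rate / rec$rate))
  }
  al <- align_peak(x)
  x <- al$x
  peak <- al$anchor
  # the robust apex estimate can sit a few samples from the literal maximum
  # on strongly asymmetric pulses; re-anchor on the maximum only when its
  # excess over the anchor sample is real (clearly above the noise floor
  # estimated from the record tails), so noisy maxima cannot jitter the
  # window placement
  tails <- c(
    x[seq_len(max(8L, length(x) %/% 20L))],
    x[(length(x) - max(8L, length(x) %/% 20L) + 1L):length(x)]
  )
  noise_hat <- stats::mad(tails)
  p_raw <- which.max(x)
  if (p_raw != peak && x[p_raw] - x[peak] > 5 * noise_hat + 1e-9 * x[p_raw]) {
    peak <- p_raw
  }
  lo <- peak - window / 2L
  idx <- lo:(lo + window - 1L)
  y <- numeric(window)
  ok <- idx >= 1L & idx <= length(x)
  y[ok] <- x[idx[ok]]
  rms <- sqrt(mean(y^2))
  if (rms == 0) abort("windowed signal is identically zero")
  structure(
    list(
      samples = y / rms, rate = target_rate, source_rate = rec$rate,
      id = rec$id, species = rec$species, window = window
    ),
    class = "conditioned_eod"
  )
}

# internal: subsample peak alignment.  The recorded peak falls between
# sample instants, and that fractional phase jitter dominates the
# within-individual variance of fine-scale wavelet coefficients.  Estimate
# the fractional offset by a parabolic fit around the sampled maximum and
# remove it with a band-limited (FFT phase-ramp) fractional delay, iterating
# to convergence so the operation is idempotent.
align_peak <- function(x, tol = 1e-4, max_iter = 8L) {
  N <- length(x)
  k <- c(0:(floor(N / 2)), -((ceiling(N / 2) - 1):1)) # FFT bin frequencies
  vertex <- function(x) {
    # mean of level-set midpoints: for each level between 30% and 70% of
    # peak, interpolate the two flank crossings of the contiguous region
    # containing the maximum and take their midpoint; average over levels.
    # Noise-robust, deterministic, and smooth in the data; its offset from
    # the true apex is a constant of the pulse shape.
    p <- which.max(x)
    fr <- seq(0.3, 0.7, by = 0.05)
    mids <- vapply(fr, function(f) {
      lev <- f * x[p]
      lo <- p
      while (lo > 1L && x[lo - 1L] >= lev) lo <- lo - 1L
      hi <- p
      while (hi < N && x[hi + 1L] >= lev) hi <- hi + 1L
      if (hi - lo < 2L || lo == 1L || hi == N) return(NA_real_)
      tl <- lo - (x[lo] - lev) / (x[lo] - x[lo - 1L])
      th <- hi + (x[hi] - lev) / (x[hi] - x[hi + 1L])
      (tl + th) / 2
    }, numeric(1))
    ok <- is.finite(mids)
    if (sum(ok) < 3L) {
      if (!any(ok)) return(NA_real_)
      return(mean(mids[ok]))
    }
    # for a monophasic pulse the midpoint at level f drifts linearly in
    # c(f) = sqrt(2 log(1/f)) away from the apex (exactly so for
    # half-Gaussian flanks); the intercept of that drift is the apex
    cf <- sqrt(2 * log(1 / fr[ok]))
    unname(stats::lm.fit(cbind(1, cf), mids[ok])$coefficients[1L])
  }
  v <- which.max(x)
  for (it in seq_len(max_iter)) {
    v <- vertex(x)
    if (!is.finite(v)) {
      v <- which.max(x)
      break
    }
    delta <- v - round(v) # fractional misalignment of the apex
    if (abs(delta) < tol) break
    X <- stats::fft(x) * exp(2i * pi * k * delta / N)
    if (N %% 2 == 0) X[N / 2 + 1L] <- Re(X[N / 2 + 1L])
    x <- Re(stats::fft(X, inverse = TRUE)) / N
  }
  list(x = x, anchor = as.integer(round(v)))
}

# internal: exact band-limited (sinc) resampling to M samples via the
# Fourier domain; the Nyquist bin is dropped, which is immaterial for
# signals that decay inside the record
fft_resample <- function(x, M) {
  N <- length(x)
  if (M == N) return(x)
  if (M < 8L) abort("resampled signal would be shorter than 8 samples")
  X <- stats::fft(x)
  h <- ceiling(min(N, M) / 2) - 1L
  Y <- complex(M)
  Y[1L] <- X[1L]
  if (h >= 1L) {
    Y[2L:(h + 1L)] <- X[2L:(h + 1L)]
    Y[(M - h + 1L):M] <- X[(N - h + 1L):N]
  }
  Re(stats::fft(Y, inverse = TRUE)) / N
}

#' @export
print.conditioned_eod <- function(x, ...) {
  cat(sprintf(
    "<conditioned_eod> %s: %d samples @ %g kHz, unit RMS, peak at %d\n",
    x$id, x$window, x$rate / 1000, which.max(x$samples)
  ))
  invisible(x)
}

#' EOD duration at a relative amplitude threshold
#'
#' Time between the first and last crossings of `threshold` times the peak
#' positive amplitude, with linear interpolation between samples. The 1%
#' threshold is the standard duration measure for monophasic pulses.
#'
#' @param rec An [eod_recording()] or `conditioned_eod`.
#' @param threshold Fraction of peak amplitude (default 0.01).
#' @return Duration in milliseconds. A signal that never exceeds the
#'   threshold level away from the peak sample returns 0 with attribute
#'   `degenerate = TRUE`.
#' @export
eod_duration <- function(rec, threshold = 0.01) {
  x <- if (inherits(rec, c("eod_recording", "conditioned_eod"))) rec$samples else rec
  rate <- if (is.list(rec)) rec$rate else attr(rec, "rate")
  if (is.null(rate)) abort("recording must carry a sampling rate")
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    abort("`threshold` must be in (0, 1)")
  }
  peak <- max(x)
  if (peak <= 0) abort("no positive peak")
  lev <- threshold * peak
  above <- which(x >= lev)
  if (length(above) <= 1L) {
    return(structure(0, degenerate = TRUE))
  }
  i1 <- above[1L]
  i2 <- above[length(above)]
  t1 <- if (i1 == 1L) 0 else {
    (i1 - 1L) - (x[i1] - lev) / (x[i1] - x[i1 - 1L])
  }
  t2 <- if (i2 == length(x)) i2 - 1 else {
    (i2 - 1L) + (x[i2] - lev) / (x[i2] - x[i2 + 1L])
  }
  1000 * (t2 - t1) / rate
}

#' DWT feature matrix of a set of EOD recordings
#'
#' Conditions each recording and stacks the full Symmlet-4 coefficient
#' vectors into an individuals-by-coefficients tibble with `id` and
#' `species` columns.
#'
#' @param recs List of [eod_recording()] objects.
#' @param target_rate,window Passed to [condition_eod()].
#' @return Tibble of class `eod_features`.
#' @export
eod_feature_matrix <- function(recs, target_rate = 96000, window = 256L) {
  stopifnot(is.list(recs), length(recs) >= 1L)
  rows <- lapply(recs, function(r) {
    co <- dwt_sym4(condition_eod(r, target_rate, window))
    dplyr::bind_cols(
      tibble(id = r$id, species = r$species),
      as_tibble(as.list(co))
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("eod_features", class(out))
  out
}

# internal: split an eod_features tibble into metadata and numeric matrix
feature_parts <- function(fm) {
  meta_cols <- intersect(c("id", "species"), names(fm))
  m <- as.matrix(fm[, setdiff(names(fm), meta_cols), drop = FALSE])
  rownames(m) <- if ("id" %in% meta_cols) fm$id else paste0("row", seq_len(nrow(fm)))
  list(meta = fm[, meta_cols, drop = FALSE], m = m)
}

#' Pairwise-ANOVA feature selection
#'
#' Scores every coefficient by its weakest pairwise between-species
#' discrimination and keeps the `k` best. For each species pair with both
#' n >= 2 the score is the one-way ANOVA F statistic; pairs involving a
#' species with a single individual use the absolute standardized mean
#' difference (|mean difference| / pooled within-species SD) instead. Each
#' coefficient's score is its minimum across pairs, so a selected feature
#' separates every pair.
#'
#' @param fm An `eod_features` tibble (or any tibble with a `species` column
#'   and numeric feature columns).
#' @param k Number of coefficients to retain (default 4).
#' @return List with `selected` (column names), `scores` (tibble), and
#'   `reduced` (tibble with metadata plus the retained columns).
#' @export
anova_reduce <- function(fm, k = 4L) {
  k <- check_count(k, "k")
  fp <- feature_parts(fm)
  if (!"species" %in% names(fp$meta)) abort("`fm` must carry a `species` column")
  sp <- fp$meta$species
  counts <- table(sp)
  if (length(counts) < 2L) abort("need >= 2 species for pairwise ANOVA")
  if (k > ncol(fp$m)) abort("`k` exceeds the number of coefficients")
  species <- names(counts)
  # pooled within-species SD per column over species with n >= 2 (fallback
  # for standardized differences when a pair member is a singleton)
  multi <- species[counts >= 2L]
  pooled_sd <- if (length(multi)) {
    num <- 0
    den <- 0
    for (s in multi) {
      xs <- fp$m[sp == s, , drop = FALSE]
      num <- num + (nrow(xs) - 1L) * apply(xs, 2L, var)
      den <- den + nrow(xs) - 1L
    }
    sqrt(num / den)
  } else {
    apply(fp$m, 2L, sd)
  }
  pooled_sd[pooled_sd == 0 | !is.finite(pooled_sd)] <- NA_real_

  pair_scores <- list()
  for (pr in utils::combn(species, 2L, simplify = FALSE)) {
    xa <- fp$m[sp == pr[1L], , drop = FALSE]
    xb <- fp$m[sp == pr[2L], , drop = FALSE]
    na <- nrow(xa)
    nb <- nrow(xb)
    if (na >= 2L && nb >= 2L) {
      ma <- colMeans(xa)
      mb <- colMeans(xb)
      va <- apply(xa, 2L, var)
      vb <- apply(xb, 2L, var)
      gm <- (na * ma + nb * mb) / (na + nb)
      ssb <- na * (ma - gm)^2 + nb * (mb - gm)^2
      ssw <- (na - 1L) * va + (nb - 1L) * vb
      f <- (ssb / 1) / (ssw / (na + nb - 2L))
      f[ssw == 0 & ssb > 0] <- Inf
      f[ssw == 0 & ssb == 0] <- 0
      s <- f
    } else {
      s <- abs(colMeans(xa) - colMeans(xb)) / pooled_sd
      s[is.na(s)] <- 0
    }
    pair_scores[[paste(pr, collapse = ":")]] <- s
  }
  score_mat <- do.call(rbind, pair_scores)
  score <- apply(score_mat, 2L, min)
  ord <- order(score, decreasing = TRUE)
  sel <- sort(ord[seq_len(k)]) # stable: original column order within the top k
  sel_names <- colnames(fp$m)[sel]
  reduced <- dplyr::bind_cols(fp$meta, as_tibble(fp$m[, sel, drop = FALSE]))
  class(reduced) <- c("eod_features", class(reduced))
  list(
    selected = sel_names,
    scores = tibble(
      coefficient = colnames(fp$m), score = unname(score),
      selected = colnames(fp$m) %in% sel_names
    ),
    reduced = reduced
  )
}

#' Single-linkage clustering of EOD feature rows
#'
#' Nearest-neighbor (single linkage) agglomeration on Euclidean distances in
#' the (reduced) coefficient space.
#'
#' @param fm An `eod_features` tibble.
#' @return Object of class `eod_clust` wrapping the [stats::hclust] tree
#'   with the species tags.
#' @export
nn_cluster <- function(fm) {
  fp <- feature_parts(fm)
  if (nrow(fp$m) < 2L) abort("need >= 2 individuals to cluster")
  hc <- hclust(dist(fp$m), method = "single")
  structure(
    list(hclust = hc, meta = fp$meta),
    class = "eod_clust"
  )
}

#' @export
print.eod_clust <- function(x, ...) {
  cat(sprintf(
    "<eod_clust> single-linkage tree of %d EODs; merge heights %.3g-%.3g\n",
    length(x$hclust$order), min(x$hclust$height), max(x$hclust$height)
  ))
  invisible(x)
}

#' Cut an EOD dendrogram into k groups
#'
#' @param x An `eod_clust`.
#' @param k Number of groups.
#' @return Tibble with `id`, `species`, `cluster`.
#' @export
cut_eod_clusters <- function(x, k) {
  stopifnot(inherits(x, "eod_clust"))
  ct <- cutree(x$hclust, k = k)
  dplyr::bind_cols(x$meta, tibble(cluster = unname(ct)))
}

#' @export
tidy.eod_clust <- function(x, ...) {
  hc <- x$hclust
  tibble(
    step = seq_along(hc$height),
    height = hc$height,
    merge1 = hc$merge[, 1L],
    merge2 = hc$merge[, 2L]
  )
}

#' Dendrogram of an EOD clustering
#'
#' @param object An `eod_clust`.
#' @param ... Unused.
#' @return A ggplot dendrogram, leaves labeled by individual and colored by
#'   species.
#' @export
autoplot.eod_clust <- function(object, ...) {
  hc <- object$hclust
  n <- length(hc$order)
  xpos <- numeric(n)
  xpos[hc$order] <- seq_len(n)
  node_x <- numeric(length(hc$height))
  node_y <- hc$height
  segs <- list()
  getx <- function(m) if (m < 0) xpos[-m] else node_x[m]
  gety <- function(m) if (m < 0) 0 else node_y[m]
  for (i in seq_along(hc$height)) {
    x1 <- getx(hc$merge[i, 1L])
    x2 <- getx(hc$merge[i, 2L])
    node_x[i] <- (x1 + x2) / 2
    segs[[i]] <- tibble(
      x = c(x1, x1, x2), xend = c(x1, x2, x2),
      y = c(gety(hc$merge[i, 1L]), hc$height[i], hc$height[i]),
      yend = c(hc$height[i], hc$height[i], gety(hc$merge[i, 2L]))
    )
  }
  leaf <- dplyr::bind_cols(object$meta, tibble(x = xpos))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = dplyr::bind_rows(segs),
      ggplot2::aes(x = .data$x, xend = .data$xend, y = .data$y, yend = .data$yend)
    ) +
    ggplot2::geom_point(
      data = leaf,
      ggplot2::aes(x = .data$x, y = 0, color = .data$species), size = 3
    ) +
    ggplot2::scale_x_continuous(
      breaks = leaf$x,
      labels = if ("id" %in% names(leaf)) leaf$id else leaf$x
    ) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1)) +
    ggplot2::labs(
      x = NULL, y = "merge height (Euclidean)",
      title = "Single-linkage clustering of EOD waveform features"
    )
}

#' Mahalanobis D2 between species centroids
#'
#' `D2(a, b) = (mu_a - mu_b)' S^-1 (mu_a - mu_b)` with `S` the pooled
#' within-species covariance over species having at least 2 individuals,
#' ridge-regularized (`S + eps I`, `eps = 1e-6 trace/dim`) when singular.
#' With no multi-member species the identity covariance is used and the
#' result flagged.
#'
#' @param fm An `eod_features` tibble (typically the reduced matrix from
#'   [anova_reduce()]).
#' @return Tibble with `species_a`, `species_b`, `d2`; attribute
#'   `identity_covariance` is TRUE when the fallback was taken.
#' @export
mahalanobis_d2 <- function(fm) {
  fp <- feature_parts(fm)
  if (!"species" %in% names(fp$meta)) abort("`fm` must carry a `species` column")
  sp <- fp$meta$species
  species <- unique(sp)
  if (length(species) < 2L) abort("need >= 2 species")
  d <- ncol(fp$m)
  multi <- species[table(sp)[species] >= 2L]
  identity_cov <- length(multi) == 0L
  if (identity_cov) {
    S <- diag(d)
    warn("no species has >= 2 recordings; using identity covariance")
  } else {
    num <- matrix(0, d, d)
    den <- 0
    for (s in multi) {
      xs <- fp$m[sp == s, , drop = FALSE]
      num <- num + (nrow(xs) - 1L) * cov(xs)
      den <- den + nrow(xs) - 1L
    }
    S <- num / den
    if (inherits(try(solve(S), silent = TRUE), "try-error") ||
        rcond_est(S) < 1e-10) {
      S <- S + diag(1e-6 * sum(diag(S)) / d, d)
    }
  }
  mu <- lapply(species, function(s) colMeans(fp$m[sp == s, , drop = FALSE]))
  names(mu) <- species
  rows <- list()
  for (pr in utils::combn(species, 2L, simplify = FALSE)) {
    d2 <- mahalanobis(rbind(mu[[pr[1L]]]), mu[[pr[2L]]], S)
    rows[[length(rows) + 1L]] <- tibble(
      species_a = pr[1L], species_b = pr[2L], d2 = unname(d2)
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "identity_covariance") <- identity_cov
  out
}

# internal: cheap reciprocal condition estimate
rcond_est <- function(S) {
  ev <- tryCatch(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
    error = function(e) c(1, 0)
  )
  if (max(ev) <= 0) return(0)
  min(ev) / max(ev)
}
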