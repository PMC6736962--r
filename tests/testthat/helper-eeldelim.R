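# Shared fixtures and independent oracles for the test suite.  Everything is
# generated in code; oracles are deliberately written as plain brute-force
# loops, independent of the package's vectorized implementations.

NUC4 <- c("A", "C", "G", "T")

# build a labeled alignment from literal sequence strings
toy_alignment <- function(seqs, lineages) {
  m <- do.call(rbind, lapply(seqs, function(s) strsplit(s, "")[[1L]]))
  rownames(m) <- names(seqs)
  eeldelim:::new_labeled_alignment(m, setNames(lineages, names(seqs)))
}

# brute-force K2P: count transitions/transversions by explicit looping
oracle_k2p <- function(a, b) {
  a <- strsplit(toupper(a), "")[[1L]]
  b <- strsplit(toupper(b), "")[[1L]]
  ts_pairs <- list(c("A", "G"), c("G", "A"), c("C", "T"), c("T", "C"))
  n <- 0L; ts <- 0L; tv <- 0L
  for (i in seq_along(a)) {
    if (!(a[i] %in% NUC4) || !(b[i] %in% NUC4)) next
    n <- n + 1L
    if (a[i] == b[i]) next
    if (any(vapply(ts_pairs, function(p) p[1] == a[i] && p[2] == b[i], TRUE))) {
      ts <- ts + 1L
    } else {
      tv <- tv + 1L
    }
  }
  P <- ts / n; Q <- tv / n
  list(d = -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q), n = n, P = P, Q = Q)
}

# brute-force diagnostic-site scan over columns
oracle_diagnostic <- function(aln, focal) {
  tags <- attr(aln, "lineage")
  m <- unclass(aln)
  out <- list()
  ingroup <- tags != "outgroup"
  frag <- which(apply(m[ingroup, , drop = FALSE], 2L, function(col) any(col %in% NUC4)))
  pos <- 0L
  for (j in frag) {
    pos <- pos + 1L
    f <- m[tags == focal, j]
    o <- m[ingroup & tags != focal, j]
    if (all(f %in% NUC4) && length(unique(f)) == 1L && !(f[1L] %in% o)) {
      out[[length(out) + 1L]] <- data.frame(position = pos, state = f[1L])
    }
  }
  if (length(out)) do.call(rbind, out) else data.frame(position = integer(), state = character())
}

# brute-force adjusted Rand index via explicit pair counting
oracle_ari <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      sa <- a[i] == a[j]; sb <- b[i] == b[j]
      if (sa && sb) s11 <- s11 + 1
      else if (!sa && !sb) s00 <- s00 + 1
      else if (sa) s10 <- s10 + 1
      else s01 <- s01 + 1
    }
  }
  tot <- choose(n, 2)
  exp_idx <- (s11 + s10) * (s11 + s01) / tot
  max_idx <- ((s11 + s10) + (s11 + s01)) / 2
  if (max_idx == exp_idx) return(1)
  (s11 - exp_idx) / (max_idx - exp_idx)
}

# simulate a plain 3-species EOD set at the published mean durations
plain_species_recs <- function(n = 5L, noise_sd = 0.02, seed = 1L) {
  durs <- c(electricus = 2.11, voltai = 1.72, varii = 1.51)
  unlist(lapply(seq_along(durs), function(i) {
    simulate_eod(
      eod_template(names(durs)[i], durs[[i]], noise_sd = noise_sd),
      n = n, seed = seed * 101L + i
    )
  }), recursive = FALSE)
}

# does a 3-cluster cut of the EOD chain match the true species exactly?
species_recovered <- function(recs) {
  red <- anova_reduce(eod_feature_matrix(recs), k = 4L)
  ct <- cut_eod_clusters(nn_cluster(red$reduced), 3L)
  tab <- table(ct$species, ct$cluster)
  all(rowSums(tab > 0) == 1L) && all(colSums(tab > 0) == 1L)
}
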