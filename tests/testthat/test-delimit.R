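# Barcode-gap partitioning and diagnostic-nucleotide screening.

make_block_matrix <- function(sizes, within, between, seed = 1) {
  # symmetric distance matrix with noisy within-block and between-block bands
  set.seed(seed)
  n <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  D <- matrix(0, n, n)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      mu <- if (lab[i] == lab[j]) within else between
      D[i, j] <- D[j, i] <- abs(mu + rnorm(1, 0, mu * 0.1 + 1e-5))
    }
  }
  rownames(D) <- colnames(D) <- paste0("x", 1:n)
  list(D = D, truth = lab)
}

test_that("all distances below the prior range give a single cluster", {
  bm <- make_block_matrix(c(4, 4), within = 0.0003, between = 0.0006)
  part <- barcode_gap_partition(bm$D, p_min = 0.001, p_max = 0.1)
  expect_equal(n_clusters(part), 1L)
})

test_that("two separated blocks are recovered and match the threshold-scan oracle", {
  bm <- make_block_matrix(c(5, 6), within = 0.003, between = 0.09)
  part <- barcode_gap_partition(bm$D, p_min = 0.001, p_max = 0.01)
  expect_equal(n_clusters(part), 2L)
  expect_equal(oracle_ari(part$cluster, bm$truth), 1)
  # oracle: exhaustive scan over every candidate threshold (midpoints of the
  # ranked distances) must contain a threshold reproducing this partition,
  # and the largest ranked gap must separate the same two blocks
  v <- sort(bm$D[upper.tri(bm$D)])
  gap_at <- which.max(diff(v))
  thr <- v[gap_at]
  comp <- eeldelim:::components_below(bm$D, thr)
  expect_equal(oracle_ari(comp, part$cluster), 1)
})

test_that("partitions are invariant to individual order", {
  bm <- make_block_matrix(c(4, 5, 3), within = 0.003, between = 0.08, seed = 3)
  part <- barcode_gap_partition(bm$D)
  perm <- sample(nrow(bm$D))
  Dp <- bm$D[perm, perm]
  part_p <- barcode_gap_partition(Dp)
  m <- dplyr::inner_join(part, part_p, by = "individual")
  expect_equal(oracle_ari(m$cluster.x, m$cluster.y), 1)
})

test_that("raising relative_gap never increases the cluster count", {
  for (s in 1:4) {
    bm <- make_block_matrix(c(4, 4, 4), within = 0.004, between = 0.07, seed = s)
    ks <- sapply(c(1, 1.5, 2.5, 4, 8), function(x) {
      n_clusters(barcode_gap_partition(bm$D, relative_gap = x))
    })
    expect_true(all(diff(ks) <= 0))
  }
})

test_that("saturated pairs sit above every threshold", {
  aln <- toy_alignment(
    c(
      a1 = strrep("A", 40), a2 = strrep("A", 40),
      b1 = strrep("C", 40), b2 = strrep("C", 40)
    ),
    c("A", "A", "B", "B")
  )
  dm <- distance_matrix(aln) # A vs C blocks are fully saturated pairs
  expect_true(any(dm$saturated))
  part <- barcode_gap_partition(dm)
  # saturated pairs can never link, so the blocks stay separate
  expect_equal(n_clusters(part), 2L)
})

test_that("the Electrophorus preset yields three clusters congruent with truth", {
  aln <- simulate_alignment(preset_electrophorus(), seed = 1)
  keep <- attr(aln, "lineage") != "outgroup"
  dm <- distance_matrix(unclass(aln)[keep, , drop = FALSE])
  part <- barcode_gap_partition(dm)
  expect_equal(n_clusters(part), 3L)
  truth <- attr(aln, "lineage")[keep]
  expect_equal(oracle_ari(part$cluster, as.integer(factor(truth))), 1)
})

test_that("diagnostic sites report fixed unique states at fragment positions", {
  aln <- toy_alignment(
    c(
      a1 = "GAAAAAAAGA", a2 = "GAAAAAAAGA",
      b1 = "AAAAAAAAGA", b2 = "AAAAAAAAGA",
      out = "GAAAAAAAGA"
    ),
    c("A", "A", "B", "B", "outgroup")
  )
  ds <- diagnostic_sites(aln, "A")
  expect_equal(ds$position, 1L)
  expect_equal(ds$state, "G")
  # identical lineages: empty set for both
  aln2 <- toy_alignment(
    c(a1 = "ACGT", a2 = "ACGT", b1 = "ACGT", b2 = "ACGT"),
    c("A", "A", "B", "B")
  )
  expect_equal(nrow(diagnostic_sites(aln2, "A")), 0L)
  expect_equal(nrow(diagnostic_sites(aln2, "B")), 0L)
  expect_error(diagnostic_sites(aln2, "C"), "absent")
})

test_that("diagnostic sites equal a brute-force column scan on random alignments", {
  set.seed(11)
  for (rep in 1:4) {
    m <- matrix(sample(c(NUC4, "-"), 6 * 20, replace = TRUE, prob = c(rep(0.23, 4), 0.08)),
      nrow = 6
    )
    rownames(m) <- paste0("s", 1:6)
    aln <- eeldelim:::new_labeled_alignment(
      m, setNames(c("A", "A", "B", "B", "C", "outgroup"), rownames(m))
    )
    for (focal in c("A", "B", "C")) {
      got <- diagnostic_sites(aln, focal)
      ora <- oracle_diagnostic(aln, focal)
      expect_equal(got$position, ora$position)
      expect_equal(got$state, ora$state)
    }
  }
})

test_that("merging non-focal lineages does not change the focal site set", {
  p <- lineage_preset(c(4, 4, 4),
    between_dist = 0.08, within_dist = 0.003, seq_length = 120
  )
  aln <- simulate_alignment(p, seed = 6)
  got <- diagnostic_sites(aln, "lineage1")
  tags <- attr(aln, "lineage")
  pooled <- ifelse(tags %in% c("lineage2", "lineage3"), "other", tags)
  aln2 <- eeldelim:::new_labeled_alignment(unclass(aln), setNames(pooled, rownames(aln)))
  got2 <- diagnostic_sites(aln2, "lineage1")
  expect_equal(got$position, got2$position)
  expect_equal(got$state, got2$state)
})

test_that("outgroup-only columns are dropped from fragment numbering", {
  aln <- toy_alignment(
    c(
      a1 = "-GAAA", a2 = "-GAAA",
      b1 = "-AAAA", b2 = "-AAAA",
      out = "CGAAA"
    ),
    c("A", "A", "B", "B", "outgroup")
  )
  ds <- diagnostic_sites(aln, "A")
  # column 2 of the alignment is position 1 of the analyzed fragment
  expect_equal(ds$position, 1L)
  expect_equal(ds$state, "G")
})

test_that("the planted Electrophorus Diagnosis sites are recovered exactly", {
  p <- preset_electrophorus()
  aln <- simulate_alignment(p, seed = 2)
  for (ln in p$lineage_names) {
    planted <- p$planted_sites[p$planted_sites$lineage == ln, ]
    got <- diagnostic_sites(aln, ln)
    found <- paste(got$position, got$state)
    expect_true(all(paste(planted$position, planted$state) %in% found))
  }
})
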