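# Single-threshold GMYC model and genealogical sorting index.

# independent gsi oracle: enumerate uniting nodes with ape path machinery
oracle_gsi <- function(tree, tips) {
  n_tip <- length(tree$tip.label)
  tipn <- match(tips, tree$tip.label)
  mrca <- ape::getMRCA(tree, tips)
  U <- unique(unlist(lapply(tipn, function(t) {
    setdiff(ape::nodepath(tree, from = t, to = mrca), seq_len(n_tip))
  })))
  deg <- tabulate(tree$edge[, 1L], nbins = n_tip + tree$Nnode) + 1L
  root <- n_tip + 1L
  deg[root] <- deg[root] - 1L
  s_obs <- sum(deg[U] - 1L)
  s_min <- 2L * (length(tipn) - 1L) - as.integer(mrca == root)
  s_max <- sum(deg[(n_tip + 1L):(n_tip + tree$Nnode)] - 1L)
  if (s_max == s_min) return(1)
  (s_max - s_obs) / (s_max - s_min)
}

test_that("the 4-tip profile likelihood equals the hand-enumerated oracle", {
  tr <- ape::read.tree(text = "((A:1,B:1):2,(C:1.5,D:1.5):1.5);")
  fit <- gmyc_fit(tr)
  prof <- fit$profile[order(-fit$profile$threshold), ]
  opt_p <- function(f) {
    grid <- seq(0, 2, by = 0.001)
    max(vapply(grid, f, numeric(1)))
  }
  # candidate above the root: one whole-tree coalescent (equals the null)
  ll_above <- opt_p(function(p) {
    S <- 1.5 * 2^p + 0.5 * 6^p + 1 * 12^p
    3 * (log(3) - log(S) - 1) + p * (log(2) + log(6) + log(12))
  })
  # T = 2.25: clusters {A,B} and {C,D}; the root is the only Yule event
  ll_225 <- opt_p(function(p) -log(0.75 * 2^p) - 1) +
    opt_p(function(p) {
      S <- 0.5 * 2^p + 1 * 2 * 2^p
      2 * (log(2) - log(S) - 1) + p * log(2) + (p * log(2) + log(2))
    })
  # T = 1.25: Yule events at 3 and 1.5; cluster {A,B} only
  ll_125 <- opt_p(function(p) {
    S <- 1.5 * 2^p + 0.25 * 3^p
    2 * (log(2) - log(S) - 1) + p * log(2)
  }) + (-1)
  # T = 0.5: all nodes Yule, four singleton tips
  ll_05 <- opt_p(function(p) {
    S <- 1.5 * 2^p + 0.5 * 3^p + 0.5 * 4^p
    3 * (log(3) - log(S) - 1) + p * (log(2) + log(3))
  })
  expect_equal(prof$loglik, c(ll_above, ll_225, ll_125, ll_05), tolerance = 1e-5)
  expect_equal(prof$k, c(1, 2, 3, 4))
  expect_equal(fit$null_loglik, ll_above, tolerance = 1e-5)
  expect_gte(fit$loglik, fit$null_loglik)
})

test_that("the 2-tip null likelihood has its closed form", {
  t2 <- ape::read.tree(text = "(A:2.5,B:2.5);")
  # single waiting time of length h with 2 lineages; profiling the rate
  # gives -log(h) - 1 independent of the exponent
  expect_equal(gmyc_null_loglik(t2), -log(2.5) - 1, tolerance = 1e-9)
})

test_that("the null likelihood matches a brute-force interval sum on 6 tips", {
  set.seed(5)
  tr <- ape::rcoal(6)
  got <- gmyc_null_loglik(tr)
  # brute force: explicit interval enumeration and dense grid over (p)
  h <- sort(unique(node_heights(tr)[7:11]), decreasing = TRUE)
  bnd <- c(h, 0)
  ll <- function(p) {
    S <- 0
    Clog <- 0
    for (i in seq_along(h)) {
      nlin <- i + 1 # lineages in the segment below the i-th deepest node
      S <- S + (bnd[i] - bnd[i + 1]) * (nlin * (nlin - 1))^p
      Clog <- Clog + log((nlin * (nlin - 1))^p)
    }
    5 * (log(5) - log(S) - 1) + Clog
  }
  expect_equal(got, max(vapply(seq(0, 2, by = 5e-4), ll, numeric(1))),
    tolerance = 1e-6
  )
})

test_that("the fitted likelihood always dominates the null (nesting)", {
  for (s in 1:6) {
    tr <- if (s %% 2 == 0) {
      simulate_tree(3, c(5, 5, 5), 5, 0.4, seed = s)
    } else {
      simulate_tree(1, 12, 5, 1, seed = s)
    }
    f <- gmyc_fit(tr)
    expect_gte(f$loglik, f$null_loglik - 1e-9)
    expect_equal(f$profile$loglik[1], f$null_loglik, tolerance = 1e-6)
    expect_true(f$n_clusters >= 1 && f$n_clusters <= length(tr$tip.label))
  }
})

test_that("strongly separated 3-species trees give 3 supported clusters", {
  tr <- simulate_tree(3, c(10, 10, 10), 5, 0.05, seed = 2)
  f <- gmyc_fit(tr)
  expect_equal(f$n_clusters, 3L)
  expect_lt(f$p_value, 0.01)
  smap <- attr(tr, "species_map")
  truth <- as.integer(factor(smap$species[match(f$clusters$tip, smap$tip)]))
  expect_equal(oracle_ari(f$clusters$cluster, truth), 1)
})

test_that("cluster count is invariant to tip relabeling and height rescaling", {
  tr <- simulate_tree(3, c(6, 6, 6), 5, 0.2, seed = 4)
  f <- gmyc_fit(tr)
  tr2 <- tr
  set.seed(1)
  tr2$tip.label <- tr$tip.label[sample(length(tr$tip.label))]
  f2 <- gmyc_fit(tr2)
  expect_equal(f2$n_clusters, f$n_clusters)
  expect_equal(f2$loglik, f$loglik, tolerance = 1e-9)
  tr3 <- tr
  tr3$edge.length <- tr$edge.length * 3.7
  f3 <- gmyc_fit(tr3)
  expect_equal(f3$n_clusters, f$n_clusters)
  expect_equal(f3$ml_n_clusters, f$ml_n_clusters)
  expect_equal(f3$threshold, f$threshold * 3.7, tolerance = 1e-9)
})

test_that("the ML threshold falls between the coalescent and speciation depths", {
  hits <- 0L
  for (s in 1:20) {
    tr <- simulate_tree(3, c(8, 8, 8), 5, 0.5, seed = 300 + s)
    f <- gmyc_fit(tr)
    T_ml <- f$profile$threshold[which.max(f$profile$loglik)]
    if (T_ml > 0.5 && T_ml < 5) hits <- hits + 1L
  }
  expect_gte(hits, 16L) # >= 80% of replicates
})

test_that("degenerate and invalid trees are handled", {
  flat <- ape::read.tree(text = "((A:1,B:1):0,(C:1,D:1):0);")
  f <- gmyc_fit(flat)
  expect_equal(f$n_clusters, 1L)
  expect_equal(f$p_value, 1)
  nonum <- ape::read.tree(text = "((A:1,B:2):1,(C:1,D:1):2);")
  expect_error(gmyc_fit(nonum), "ultrametric")
  expect_error(gmyc_fit(ape::read.tree(text = "(A:1,B:1,C:1);")), "4 tips")
})

test_that("gsi is 1 exactly for monophyletic groups and matches the oracle", {
  tr <- ape::read.tree(text = "((A1:1,A2:1):1,(B1:1,B2:1):1);")
  expect_equal(gsi(tr, c("A1", "A2")), 1)
  expect_equal(gsi(tr, c("A1", "B1")), oracle_gsi(tr, c("A1", "B1")))
  expect_equal(gsi(tr, c("A1", "B1")), 0) # maximal dispersion on 4 tips

  # both directions of the equivalence, over enumerated subsets
  set.seed(8)
  for (rep in 1:3) {
    tr8 <- ape::rcoal(8)
    for (n in 2:3) {
      for (grp in utils::combn(tr8$tip.label, n, simplify = FALSE)) {
        g <- gsi(tr8, grp)
        expect_gte(g, 0)
        expect_lte(g, 1)
        mono <- ape::is.monophyletic(tr8, grp)
        expect_equal(g == 1, mono)
        expect_equal(g, oracle_gsi(tr8, grp), tolerance = 1e-12)
      }
    }
  }
})

test_that("gsi rejects singleton and non-proper groups", {
  tr <- ape::read.tree(text = "((A1:1,A2:1):1,(B1:1,B2:1):1);")
  expect_error(gsi(tr, "A1"), "size 1")
  expect_error(gsi(tr, tr$tip.label), "proper subset")
})

test_that("gsi permutation p-values are reproducible and calibrated", {
  tr <- simulate_tree(3, c(10, 10, 10), 5, 0.3, seed = 12)
  smap <- attr(tr, "species_map")
  grp <- smap$tip[smap$species == "sp1"]
  r1 <- gsi_pvalue(tr, grp, n_perm = 200, seed = 77)
  r2 <- gsi_pvalue(tr, grp, n_perm = 200, seed = 77)
  expect_identical(r1$p_value, r2$p_value)
  expect_equal(r1$gsi, 1)
  # random groups: p roughly uniform across seeds
  set.seed(99)
  ps <- sapply(1:40, function(i) {
    g <- sample(tr$tip.label, 8)
    gsi_pvalue(tr, g, n_perm = 150, seed = i)$p_value
  })
  expect_gt(mean(ps), 0.25)
  expect_lt(mean(ps), 0.75)
})

test_that("haplotype deduplication keeps the first of each identical sequence", {
  aln <- toy_alignment(
    c(a1 = "ACGT", a2 = "ACGT", b1 = "AGGT", b2 = "ACGT"),
    c("A", "A", "B", "B")
  )
  dd <- dedupe_haplotypes(aln)
  expect_equal(rownames(dd), c("a1", "b1"))
})
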