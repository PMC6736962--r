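# EOD waveform pipeline: conditioning, duration, DWT, feature selection,
# clustering, Mahalanobis D2.

test_that("conditioning yields unit RMS, fixed peak index and scale invariance", {
  tpl <- eod_template("x", 1.8, noise_sd = 0)
  rec <- simulate_eod(tpl, 1, seed = 3)[[1]]
  ce <- condition_eod(rec)
  expect_length(ce$samples, 256L)
  expect_equal(sqrt(mean(ce$samples^2)), 1, tolerance = 1e-9)
  expect_equal(which.max(ce$samples), 129L)
  rec7 <- rec
  rec7$samples <- rec$samples * 7
  expect_equal(condition_eod(rec7)$samples, ce$samples, tolerance = 1e-12)
})

test_that("conditioning is idempotent at the same rate", {
  rec <- simulate_eod(eod_template("x", 1.4, noise_sd = 0.01), 1, seed = 9)[[1]]
  ce <- condition_eod(rec)
  ce2 <- condition_eod(
    eod_recording(ce$samples, ce$rate, id = ce$id, species = ce$species)
  )
  expect_equal(ce2$samples, ce$samples, tolerance = 1e-9)
})

test_that("band-limited resampling matches the analytic waveform", {
  # modulated pulse with a unique positive peak, known in closed form
  f0 <- 2000
  env <- function(t, tp) exp(-((t - tp) / 8e-4)^2)
  tp <- 0.01
  t96 <- (0:2047) / 96000
  rec <- eod_recording(env(t96, tp) * (1.5 + cos(2 * pi * f0 * (t96 - tp))), 96000)
  ce <- condition_eod(rec, target_rate = 48000)
  # oracle: the same analytic signal sampled directly at 48 kHz
  t48 <- (0:1023) / 48000
  ref <- condition_eod(
    eod_recording(env(t48, tp) * (1.5 + cos(2 * pi * f0 * (t48 - tp))), 48000),
    target_rate = 48000
  )
  mid <- 29:228 # away from window edges
  expect_lt(max(abs(ce$samples[mid] - ref$samples[mid])) / max(ref$samples), 1e-3)
})

test_that("polarity and degenerate signals are caught", {
  neg <- eod_recording(-simulate_eod(eod_template("x", 1.4, noise_sd = 0), 1, seed = 1)[[1]]$samples, 96000)
  expect_error(condition_eod(neg), "polarity|negative")
  flipped <- condition_eod(neg, flip = TRUE)
  expect_equal(which.max(flipped$samples), 129L)
  expect_error(condition_eod(eod_recording(rep(0, 512), 96000)), "zero")
})

test_that("duration measurement matches analytic thresholds", {
  rate <- 96000
  # rectangular pulse of width w
  w <- 1.25e-3
  x <- numeric(1024)
  x[300:(300 + round(w * rate) - 1L)] <- 1
  d <- eod_duration(eod_recording(x, rate))
  expect_lt(abs(d - w * 1000), 2 * 1000 / rate)
  # Gaussian pulse: duration = 2 sigma sqrt(2 ln 100)
  sigma <- 0.2e-3
  t <- (0:2047) / rate
  g <- exp(-(t - 0.01)^2 / (2 * sigma^2))
  dg <- eod_duration(eod_recording(g, rate))
  expect_equal(dg, 2 * sigma * sqrt(2 * log(100)) * 1000, tolerance = 1e-3)
  expect_equal(dg, 1.2139, tolerance = 1e-3)
  # amplitude invariance is exact
  expect_equal(eod_duration(eod_recording(5 * g, rate)), dg)
  # a lone spike has degenerate (zero) duration
  spike <- numeric(64)
  spike[32] <- 1
  ds <- eod_duration(eod_recording(spike, rate))
  expect_equal(as.numeric(ds), 0)
  expect_true(attr(ds, "degenerate"))
})

test_that("the Symmlet-4 DWT is orthonormal and invertible", {
  expect_equal(dwt_sym4(numeric(256)), setNames(numeric(256), names(dwt_sym4(numeric(256)))))
  set.seed(21)
  for (rep in 1:3) {
    x <- rnorm(256)
    co <- dwt_sym4(x)
    expect_equal(sum(co^2), sum(x^2), tolerance = 1e-9) # Parseval
    expect_equal(idwt_sym4(co), x, tolerance = 1e-9) # exact inverse
  }
  imp <- numeric(256)
  imp[1] <- 1
  expect_equal(idwt_sym4(dwt_sym4(imp)), imp, tolerance = 1e-9)
  expect_error(dwt_sym4(numeric(100)), "power of two")
})

test_that("DWT coefficients match the reference periodized transform", {
  # frozen coefficients computed with PyWavelets (sym4, mode='periodization',
  # wavedec level 4) for this exact input
  x <- round(sin((0:15) * 0.7) + 0.1 * (0:15), 6)
  co <- dwt_sym4(x)
  expect_equal(unname(co[1]), 3.395319249999, tolerance = 1e-9)
  expect_equal(unname(co[2]), 0.414912389214, tolerance = 1e-9)
  expect_equal(unname(co[3:4]), c(-0.189666236691, -2.753956598542), tolerance = 1e-9)
  expect_equal(
    unname(co[5:8]),
    c(-0.288281378833, 0.642889806514, -0.389276091096, 0.023630844585),
    tolerance = 1e-9
  )
  expect_equal(
    unname(co[9:16]),
    c(
      0.517577973332, -0.203186772638, -0.017535869585, 0.09384174671,
      0.049435972428, -0.077036974065, -0.055618690024, 0.014873503493
    ),
    tolerance = 1e-9
  )
  expect_equal(names(co)[1:4], c("a4", "d4_1", "d3_1", "d3_2"))
})

test_that("pairwise ANOVA scores match a textbook one-way ANOVA", {
  set.seed(3)
  fm <- dplyr::bind_cols(
    tibble::tibble(
      id = paste0("i", 1:7),
      species = c("a", "a", "a", "b", "b", "b", "b")
    ),
    tibble::tibble(f1 = c(1, 2, 3, 7, 8, 9, 10), f2 = rnorm(7))
  )
  class(fm) <- c("eod_features", class(fm))
  red <- anova_reduce(fm, k = 1)
  # independent oracle: stats::aov
  f_ora <- function(v) {
    g <- factor(fm$species)
    summary(stats::aov(v ~ g))[[1]][["F value"]][1]
  }
  expect_equal(
    red$scores$score[red$scores$coefficient == "f1"], f_ora(fm$f1),
    tolerance = 1e-9
  )
  expect_equal(
    red$scores$score[red$scores$coefficient == "f2"], f_ora(fm$f2),
    tolerance = 1e-9
  )
  expect_equal(red$selected, "f1") # the separating feature wins
})

test_that("a perfectly separating coefficient is ranked first among noise", {
  set.seed(14)
  n <- c(a = 4, b = 4, c = 4)
  sp <- rep(names(n), n)
  sep <- ifelse(sp == "a", 0, ifelse(sp == "b", 10, 20)) + rnorm(12, 0, 0.1)
  noise <- matrix(rnorm(12 * 9), 12)
  fm <- dplyr::bind_cols(
    tibble::tibble(id = paste0("i", 1:12), species = sp),
    tibble::as_tibble(as.data.frame(cbind(sep = sep, noise)))
  )
  class(fm) <- c("eod_features", class(fm))
  red <- anova_reduce(fm, k = 3)
  expect_true("sep" %in% red$selected)
  expect_equal(red$scores$coefficient[which.max(red$scores$score)], "sep")
})

test_that("the paper-shaped 7-individual set reduces to exactly 4 columns", {
  recs <- c(
    simulate_eod(eod_template("electricus", 2.11, noise_sd = 0.01), 2, seed = 31),
    simulate_eod(eod_template("varii", 1.51, noise_sd = 0.01), 4, seed = 32),
    simulate_eod(eod_template("voltai", 1.72, noise_sd = 0.01), 1, seed = 33)
  )
  fm <- eod_feature_matrix(recs)
  expect_equal(ncol(fm) - 2L, 256L)
  red <- anova_reduce(fm, k = 4)
  expect_length(red$selected, 4L)
  expect_equal(ncol(red$reduced) - 2L, 4L)
  expect_error(anova_reduce(fm, k = 300), "exceeds")
  fm1 <- fm[fm$species == "varii", ]
  class(fm1) <- class(fm)
  expect_error(anova_reduce(fm1), ">= 2 species")
})

test_that("single linkage follows the hand-traced merge order", {
  fm <- dplyr::bind_cols(
    tibble::tibble(id = paste0("p", 1:4), species = "s"),
    tibble::tibble(f = c(0, 1, 10, 11))
  )
  class(fm) <- c("eod_features", class(fm))
  cl <- nn_cluster(fm)
  expect_equal(sort(cl$hclust$height), c(1, 1, 9))
  ct <- cut_eod_clusters(cl, 2)
  expect_equal(ct$cluster, c(1, 1, 2, 2))
  # duplicate rows merge at height zero
  fm2 <- fm
  fm2$f <- c(3, 3, 8, 9)
  cl2 <- nn_cluster(fm2)
  expect_equal(min(cl2$hclust$height), 0)
})

test_that("Mahalanobis D2 reduces to Euclidean under identity covariance", {
  base <- rbind(
    c(sqrt(1.5), 0), c(-sqrt(1.5), 0), c(0, sqrt(1.5)), c(0, -sqrt(1.5))
  ) # sample covariance = identity
  fm <- dplyr::bind_cols(
    tibble::tibble(
      id = paste0("i", 1:8),
      species = rep(c("a", "b"), each = 4)
    ),
    tibble::as_tibble(as.data.frame(rbind(base, sweep(base, 2, c(3, 4), `+`))))
  )
  names(fm)[3:4] <- c("f1", "f2")
  class(fm) <- c("eod_features", class(fm))
  d2 <- mahalanobis_d2(fm)
  expect_equal(d2$d2, 25, tolerance = 1e-9)
})

test_that("D2 equals an explicit matrix-inverse computation and is affine invariant", {
  set.seed(6)
  m <- matrix(rnorm(30 * 3), 30)
  sp <- rep(c("a", "b", "c"), each = 10)
  m[sp == "b", 1] <- m[sp == "b", 1] + 2
  m[sp == "c", 2] <- m[sp == "c", 2] + 3
  fm <- dplyr::bind_cols(
    tibble::tibble(id = paste0("i", 1:30), species = sp),
    tibble::as_tibble(as.data.frame(m))
  )
  class(fm) <- c("eod_features", class(fm))
  d2 <- mahalanobis_d2(fm)
  # explicit pooled covariance + solve()
  S <- Reduce(`+`, lapply(split(as.data.frame(m), sp), function(x) 9 * cov(x))) / 27
  mu <- lapply(split(as.data.frame(m), sp), colMeans)
  hand <- function(a, b) {
    dd <- unlist(mu[[a]]) - unlist(mu[[b]])
    as.numeric(t(dd) %*% solve(S) %*% dd)
  }
  expect_equal(
    d2$d2,
    c(hand("a", "b"), hand("a", "c"), hand("b", "c")),
    tolerance = 1e-9
  )
  # full-rank affine transform leaves D2 unchanged
  A <- matrix(c(2, 0.5, -1, 0.3, 1.5, 0.2, 0, -0.7, 1.1), 3)
  fm2 <- fm
  fm2[, 3:5] <- as.data.frame(m %*% A + matrix(rep(c(5, -2, 1), each = 30), 30))
  d2b <- mahalanobis_d2(fm2)
  expect_equal(d2b$d2, d2$d2, tolerance = 1e-6)
})

test_that("all-singleton species fall back to identity covariance with a warning", {
  fm <- dplyr::bind_cols(
    tibble::tibble(id = c("i1", "i2"), species = c("a", "b")),
    tibble::tibble(f1 = c(0, 3), f2 = c(0, 4))
  )
  class(fm) <- c("eod_features", class(fm))
  expect_warning(d2 <- mahalanobis_d2(fm), "identity")
  expect_equal(d2$d2, 25)
  expect_true(attr(d2, "identity_covariance"))
})

test_that("the three species separate at the 3-cluster cut", {
  ok <- vapply(1:10, function(s) species_recovered(plain_species_recs(seed = s)),
    logical(1)
  )
  expect_gte(mean(ok), 0.9)
})
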