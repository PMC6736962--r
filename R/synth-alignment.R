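# Seeded simulation of COI-like multi-lineage alignments under a Kimura
# two-parameter substitution process, with optional planted diagnostic sites.

NUC <- c("A", "C", "G", "T")
TS_PARTNER <- c(3L, 4L, 1L, 2L) # A<->G, C<->T
TV_FIRST <- c(2L, 1L, 2L, 1L)
TV_SECOND <- c(4L, 3L, 4L, 3L)

#' Describe a multi-lineage alignment simulation
#'
#' A lineage preset fixes the statistical structure of a simulated barcode
#' alignment: number of lineages, sample sizes, sequence length, the target
#' mean K2P divergences between and within lineages (substitutions/site), the
#' transition/transversion rate ratio, and optionally a set of diagnostic
#' sites planted so that one lineage is fixed for a state absent from all
#' other ingroup individuals.
#'
#' @param n_per_lineage Integer vector, individuals per lineage.
#' @param between_dist Either a symmetric matrix of target between-lineage
#'   mean K2P distances, or a vector in `combn(n_lineages, 2)` column order.
#' @param within_dist Numeric vector of target within-lineage mean K2P
#'   distances (recycled).
#' @param seq_length Number of sites (default 569, a COI barcode fragment).
#' @param kappa Transition/transversion rate ratio (default 4).
#' @param planted_sites Optional data frame with columns `lineage`,
#'   `position`, `state`: sites overwritten post-simulation so that the focal
#'   lineage is fixed for `state` and no other ingroup individual carries it.
#' @param lineage_names Optional character vector of lineage names.
#' @return An object of class `lineage_preset`.
#' @export
#' @examples
#' p <- lineage_preset(c(5, 5), between_dist = 0.08, within_dist = 0.003)
#' aln <- simulate_alignment(p, seed = 1)
lineage_preset <- function(n_per_lineage,
                           between_dist,
                           within_dist,
                           seq_length = 569L,
                           kappa = 4,
                           planted_sites = NULL,
                           lineage_names = NULL) {
  L <- length(n_per_lineage)
  if (L < 1L) abort("need at least one lineage")
  n_per_lineage <- vapply(n_per_lineage, check_count, integer(1), name = "n_per_lineage")
  seq_length <- check_count(seq_length, "seq_length", min = 1L)
  if (!is.numeric(kappa) || kappa <= 0) abort("`kappa` must be positive")
  if (is.null(lineage_names)) lineage_names <- paste0("lineage", seq_len(L))
  if (length(lineage_names) != L) abort("`lineage_names` has wrong length")

  within_dist <- rep_len(as.numeric(within_dist), L)
  B <- matrix(0, L, L, dimnames = list(lineage_names, lineage_names))
  if (L > 1L) {
    if (is.matrix(between_dist)) {
      if (!all(dim(between_dist) == c(L, L)) ||
          max(abs(between_dist - t(between_dist))) > 1e-12) {
        abort("`between_dist` matrix must be symmetric of dimension n_lineages")
      }
      B[] <- as.numeric(between_dist)
    } else {
      idx <- combn(L, 2L)
      bv <- rep_len(as.numeric(between_dist), ncol(idx))
      for (k in seq_len(ncol(idx))) {
        B[idx[1L, k], idx[2L, k]] <- bv[k]
        B[idx[2L, k], idx[1L, k]] <- bv[k]
      }
    }
    diag(B) <- 0
  }

  all_d <- c(B[upper.tri(B)], within_dist)
  if (any(all_d < 0) || any(all_d >= 0.5)) {
    abort("all target distances must lie in [0, 0.5)")
  }
  if (L > 1L) {
    for (i in seq_len(L - 1L)) for (j in (i + 1L):L) {
      b <- B[i, j]
      w <- max(within_dist[i], within_dist[j])
      if (!(b > w || (b == 0 && w == 0))) {
        abort(sprintf(
          "infeasible targets: within-lineage divergence (%g) must be below the %s-%s between-lineage target (%g)",
          w, lineage_names[i], lineage_names[j], b
        ))
      }
    }
  }

  if (!is.null(planted_sites)) {
    planted_sites <- as_tibble(planted_sites)
    need <- c("lineage", "position", "state")
    if (!all(need %in% names(planted_sites))) {
      abort("`planted_sites` needs columns lineage, position, state")
    }
    if (!all(planted_sites$lineage %in% lineage_names)) {
      abort("planted lineage tag not among lineage names")
    }
    if (!all(planted_sites$state %in% NUC)) abort("planted states must be A/C/G/T")
    if (any(planted_sites$position < 1L) ||
        any(planted_sites$position > seq_length)) {
      abort("`seq_length` must be at least the largest planted position")
    }
    key <- paste(planted_sites$position, planted_sites$state)
    if (anyDuplicated(key)) {
      abort("planted-site conflict: two lineages plant the same state at the same position")
    }
    split_pos <- split(planted_sites$state, planted_sites$position)
    if (any(lengths(split_pos) >= length(NUC))) {
      abort("too many distinct states planted at one position")
    }
  }

  structure(
    list(
      n_lineages = L,
      n_per_lineage = n_per_lineage,
      seq_length = seq_length,
      between_dist = B,
      within_dist = setNames(within_dist, lineage_names),
      kappa = kappa,
      planted_sites = planted_sites,
      lineage_names = lineage_names
    ),
    class = "lineage_preset"
  )
}

#' @export
print.lineage_preset <- function(x, ...) {
  cat("<lineage_preset> ", x$n_lineages, " lineages (",
    paste(x$lineage_names, collapse = ", "), "), ",
    sum(x$n_per_lineage), " individuals, ", x$seq_length, " bp\n",
    sep = ""
  )
  invisible(x)
}

#' Electrophorus-like simulation preset
#'
#' Three COI lineages at the divergences estimated for the three electric eel
#' species (between-lineage means 6.6/9.8/9.3%, within-lineage means
#' 0.02/0.31/0.32%), sample sizes 19/43/45, a 569-bp fragment, and the
#' published per-species diagnostic nucleotides planted at their fragment
#' positions.
#'
#' @param planted Logical; include the diagnostic-site plan (default TRUE).
#' @return A [lineage_preset()].
#' @export
preset_electrophorus <- function(planted = TRUE) {
  sites <- NULL
  if (planted) {
    sites <- tibble(
      lineage = c(
        rep("electricus", 10L),
        rep("varii", 11L),
        rep("voltai", 8L)
      ),
      position = c(
        8L, 50L, 76L, 77L, 107L, 119L, 182L, 272L, 494L, 560L,
        64L, 80L, 146L, 164L, 190L, 251L, 467L, 512L, 517L, 536L, 569L,
        25L, 29L, 50L, 86L, 140L, 230L, 338L, 545L
      ),
      state = c(
        "G", "A", "T", "T", "T", "C", "C", "G", "G", "A",
        "A", "A", "G", "G", "T", "A", "A", "C", "T", "A", "C",
        "A", "C", "C", "C", "C", "A", "A", "C"
      )
    )
  }
  lineage_preset(
    n_per_lineage = c(19L, 43L, 45L),
    between_dist = c(0.066, 0.098, 0.093),
    within_dist = c(0.0002, 0.0031, 0.0032),
    seq_length = 569L,
    kappa = 4,
    planted_sites = sites,
    lineage_names = c("electricus", "voltai", "varii")
  )
}

# K80 transition probabilities for one branch of evolutionary distance d
# (expected substitutions/site) at ts/tv rate ratio kappa; mutates the
# integer-coded sequence in a single vectorized pass.
evolve_k80 <- function(x, d, kappa) {
  if (d <= 0) return(x)
  bt <- d / (kappa + 2)
  e1 <- exp(-4 * bt)
  e2 <- exp(-2 * (kappa + 1) * bt)
  P <- 0.25 + 0.25 * e1 - 0.5 * e2 # transition probability
  Q <- 0.5 - 0.5 * e1 # total transversion probability
  u <- runif(length(x))
  ts <- u < P
  tv <- !ts & u < P + Q
  if (any(ts)) x[ts] <- TS_PARTNER[x[ts]]
  if (any(tv)) {
    pick <- runif(sum(tv)) < 0.5
    xt <- x[tv]
    xt[pick] <- TV_FIRST[xt[pick]]
    xt[!pick] <- TV_SECOND[xt[!pick]]
    x[tv] <- xt
  }
  x
}

# expected K80 transition/transversion proportions after distance d
k80_props <- function(d, kappa) {
  bt <- unname(d) / (kappa + 2)
  e1 <- exp(-4 * bt)
  e2 <- exp(-2 * (kappa + 1) * bt)
  c(P = 0.25 + 0.25 * e1 - 0.5 * e2, Q = 0.5 - 0.5 * e1)
}

# Planted diagnostic columns replace background variation with forced fixed
# differences, which would inflate realized between-lineage divergences
# above their targets.  Recalibrate the background targets in (P, Q) space:
# subtract the forced transition/transversion counts of each pair from the
# expected substitution counts at the full target, and spread the remainder
# over the unplanted columns.  Within-lineage targets are scaled up slightly
# because a lineage's own planted columns are constant within it.
adjust_targets_for_planting <- function(preset) {
  sites <- preset$planted_sites
  L <- preset$seq_length
  kap <- preset$kappa
  B <- preset$between_dist
  W <- preset$within_dist
  nl <- preset$n_lineages
  pos_by_lineage <- split(sites$position, sites$lineage)
  state_at <- setNames(sites$state, paste(sites$lineage, sites$position))
  for (i in seq_len(nl)) {
    for (j in seq_len(nl)) {
      if (j <= i) next
      li <- preset$lineage_names[i]
      lj <- preset$lineage_names[j]
      pi <- pos_by_lineage[[li]] %||% integer()
      pj <- pos_by_lineage[[lj]] %||% integer()
      u <- union(pi, pj)
      if (length(u) == 0L) next
      n_ts <- 0L
      n_tv <- 0L
      for (p in u) {
        if (p %in% pi && p %in% pj) {
          si <- state_at[[paste(li, p)]]
          sj <- state_at[[paste(lj, p)]]
          if (NUC[TS_PARTNER[match(si, NUC)]] == sj) n_ts <- n_ts + 1L else n_tv <- n_tv + 1L
        } else {
          n_ts <- n_ts + 1L # forced alternative states prefer the transition partner
        }
      }
      pq <- k80_props(B[i, j], kap)
      nbg <- L - length(u)
      Pb <- (pq[["P"]] * L - n_ts) / nbg
      Qb <- (pq[["Q"]] * L - n_tv) / nbg
      if (Pb < 0 || Qb < 0) {
        abort(sprintf(
          "planted diagnostic sites alone exceed the %s-%s divergence target", li, lj
        ))
      }
      B[i, j] <- B[j, i] <- k2p_core(Pb, Qb)
    }
    k_own <- length(pos_by_lineage[[preset$lineage_names[i]]] %||% integer())
    if (k_own > 0L && W[i] > 0) {
      pqw <- k80_props(W[i], kap)
      W[i] <- k2p_core(pqw[["P"]] * L / (L - k_own), pqw[["Q"]] * L / (L - k_own))
    }
  }
  list(between = B, within = W)
}

# Solve per-lineage stem distances b so that b_i + b_j + t_i + t_j equals the
# target between-lineage distance for every pair (least squares for > 3
# lineages; exact for 2 or 3).
solve_stem_lengths <- function(B, tip_len) {
  L <- nrow(B)
  if (L == 1L) return(0)
  idx <- combn(L, 2L)
  y <- B[t(idx)] - tip_len[idx[1L, ]] - tip_len[idx[2L, ]]
  if (any(y < -1e-12)) abort("infeasible targets: within >= between for some pair")
  A <- matrix(0, ncol(idx), L)
  for (k in seq_len(ncol(idx))) A[k, idx[, k]] <- 1
  if (L == 2L) {
    b <- rep(y[1L] / 2, 2L)
  } else {
    b <- as.numeric(solve(crossprod(A), crossprod(A, y)))
  }
  pmax(b, 0)
}

#' Simulate a labeled multi-lineage alignment
#'
#' Evolves sequences on a three-level genealogy (outgroup stem, star splits
#' between lineage ancestors, star coalescent within lineages) under a Kimura
#' two-parameter substitution process, with branch lengths chosen so that the
#' expected pairwise K2P distances between and within lineages equal the
#' preset targets. Planted diagnostic sites are applied after simulation and
#' are guaranteed to be fixed in the focal lineage and absent elsewhere in the
#' ingroup.
#'
#' @param preset A [lineage_preset()].
#' @param seed Integer seed; identical seed and preset give bit-identical
#'   output.
#' @param n_outgroup Number of outgroup sequences (>= 1).
#' @param outgroup_dist Evolutionary distance from the ingroup ancestor to the
#'   outgroup; default 1.5 x the largest between-lineage target (floor 0.15).
#' @return A `labeled_alignment`: a character matrix of sequences (rows =
#'   individuals) with lineage tags; see [alignment_tags()].
#' @export
simulate_alignment <- function(preset, seed, n_outgroup = 1L,
                               outgroup_dist = NULL) {
  stopifnot(inherits(preset, "lineage_preset"))
  n_outgroup <- check_count(n_outgroup, "n_outgroup")
  if (is.null(outgroup_dist)) {
    outgroup_dist <- max(1.5 * max(preset$between_dist), 0.15)
  }
  L <- preset$seq_length
  targets <- if (is.null(preset$planted_sites)) {
    list(between = preset$between_dist, within = preset$within_dist)
  } else {
    adjust_targets_for_planting(preset)
  }
  with_seed(seed, {
    tip_len <- targets$within / 2
    stems <- solve_stem_lengths(targets$between, tip_len)
    root <- sample.int(4L, L, replace = TRUE)
    rows <- list()
    tags <- character()
    for (i in seq_len(preset$n_lineages)) {
      anc <- evolve_k80(root, stems[i], preset$kappa)
      nm <- preset$lineage_names[i]
      for (j in seq_len(preset$n_per_lineage[i])) {
        id <- sprintf("%s_tip%d", nm, j)
        rows[[id]] <- evolve_k80(anc, tip_len[i], preset$kappa)
        tags[id] <- nm
      }
    }
    for (j in seq_len(n_outgroup)) {
      id <- sprintf("outgroup_tip%d", j)
      rows[[id]] <- evolve_k80(root, outgroup_dist, preset$kappa)
      tags[id] <- "outgroup"
    }
    m <- do.call(rbind, rows)
    m <- matrix(NUC[m], nrow = nrow(m), dimnames = list(names(rows), NULL))
    aln <- new_labeled_alignment(m, tags)
    if (!is.null(preset$planted_sites)) {
      aln <- plant_sites(aln, preset$planted_sites)
    }
    attr(aln, "preset") <- preset
    attr(aln, "seed") <- seed
    aln
  })
}

new_labeled_alignment <- function(seq_matrix, tags) {
  stopifnot(is.matrix(seq_matrix), !is.null(rownames(seq_matrix)))
  structure(
    seq_matrix,
    lineage = tags[rownames(seq_matrix)],
    class = c("labeled_alignment", "matrix", "array")
  )
}

# Overwrite planted columns: focal lineage fixed for the planted state; any
# other ingroup individual carrying a state planted at that position is moved
# to the first unplanted nucleotide. Planted sites therefore survive later
# screening exactly.
plant_sites <- function(aln, sites) {
  tags <- attr(aln, "lineage")
  ingroup <- tags != "outgroup"
  for (p in unique(sites$position)) {
    here <- sites[sites$position == p, ]
    planted_states <- here$state
    cand <- setdiff(NUC, planted_states)
    # prefer the transition partner of the planted state so forced
    # differences mimic the transition-rich substitution mix
    ts_alt <- NUC[TS_PARTNER[match(here$state[1L], NUC)]]
    alt <- if (ts_alt %in% cand) ts_alt else cand[1L]
    planted_rows <- tags %in% here$lineage
    for (k in seq_len(nrow(here))) {
      aln[tags == here$lineage[k], p] <- here$state[k]
    }
    clash <- ingroup & !planted_rows & aln[, p] %in% planted_states
    if (any(clash)) aln[clash, p] <- alt
  }
  aln
}

#' Lineage tags of a labeled alignment
#'
#' @param aln A `labeled_alignment`.
#' @return Tibble with columns `individual`, `lineage`, `is_outgroup`.
#' @export
alignment_tags <- function(aln) {
  stopifnot(inherits(aln, "labeled_alignment"))
  tags <- attr(aln, "lineage")
  tibble(
    individual = rownames(aln),
    lineage = unname(tags),
    is_outgroup = unname(tags == "outgroup")
  )
}

#' @export
print.labeled_alignment <- function(x, ...) {
  tags <- attr(x, "lineage")
  cat("<labeled_alignment> ", nrow(x), " sequences x ", ncol(x), " sites; lineages: ",
    paste(sprintf("%s (%d)", names(table(tags)), table(tags)), collapse = ", "),
    "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
as_tibble.labeled_alignment <- function(x, ...) {
  tags <- attr(x, "lineage")
  tibble(
    individual = rownames(x),
    lineage = unname(tags),
    sequence = apply(unclass(x), 1L, paste0, collapse = "")
  )
}

#' Collapse an alignment to unique haplotypes
#'
#' Keeps the first individual carrying each distinct sequence; used to prepare
#' tree-based delimitation inputs where duplicate haplotypes would distort
#' branching-rate estimates.
#'
#' @param aln A `labeled_alignment`.
#' @return A `labeled_alignment` with duplicate sequences removed.
#' @export
dedupe_haplotypes <- function(aln) {
  stopifnot(inherits(aln, "labeled_alignment"))
  key <- apply(unclass(aln), 1L, paste0, collapse = "")
  keep <- !duplicated(key)
  new_labeled_alignment(unclass(aln)[keep, , drop = FALSE], attr(aln, "lineage")[keep])
}

#' Write a labeled alignment to FASTA
#'
#' Sequence identifiers encode the lineage tag as `lineage|individual`.
#'
#' @param aln A `labeled_alignment`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(aln, path) {
  stopifnot(inherits(aln, "labeled_alignment"))
  tags <- attr(aln, "lineage")
  ids <- sprintf("%s|%s", tags, rownames(aln))
  seqs <- apply(unclass(aln), 1L, paste0, collapse = "")
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  invisible(path)
}

#' Read a labeled alignment from FASTA
#'
#' Expects identifiers of the form `lineage|individual` (as written by
#' [write_alignment_fasta()]); a bare identifier is given lineage tag
#' `"unknown"` unless a label map is supplied.
#'
#' @param path FASTA file of equal-length aligned sequences.
#' @param label_map Optional data frame with columns `individual`, `lineage`
#'   overriding tags encoded in the identifiers.
#' @return A `labeled_alignment`.
#' @export
read_alignment_fasta <- function(path, label_map = NULL) {
  dna <- ape::read.FASTA(path)
  m <- toupper(do.call(rbind, lapply(as.character(dna), identity)))
  ids <- names(dna)
  has_tag <- grepl("|", ids, fixed = TRUE)
  tags <- ifelse(has_tag, sub("\\|.*$", "", ids), "unknown")
  ind <- ifelse(has_tag, sub("^[^|]*\\|", "", ids), ids)
  rownames(m) <- ind
  tags <- setNames(tags, ind)
  if (!is.null(label_map)) {
    label_map <- as.data.frame(label_map)
    tags[label_map$individual] <- label_map$lineage
  }
  new_labeled_alignment(m, tags)
}
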