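# Seeded simulation of ultrametric trees with deep Yule-like splits between
# species and shallow rescaled coalescents within species.

#' Simulate an ultrametric species/gene tree
#'
#' Builds a rooted ultrametric tree in which species-level splits follow a
#' pure-birth (Yule) spacing constrained to depths in
#' `[speciation_depth / 2, speciation_depth]`, and each species carries a
#' standard coalescent genealogy rescaled so its root is no deeper than
#' `coalescent_depth`. Every simulated species is monophyletic by
#' construction.
#'
#' @param n_species Number of species (>= 1).
#' @param tips_per_species Integer vector of tips per species (recycled).
#' @param speciation_depth Depth (time before present) of the species-level
#'   root.
#' @param coalescent_depth Upper bound for within-species coalescent root
#'   heights; must be smaller than `speciation_depth`.
#' @param seed Integer seed; identical inputs give bit-identical trees.
#' @param species_names Optional species names (default `sp1`, `sp2`, ...).
#' @return An [ape::phylo] ultrametric tree with tip labels
#'   `<species>_tip<N>` and a `species_map` attribute (tibble `tip`,
#'   `species`).
#' @export
#' @examples
#' tr <- simulate_tree(3, c(5, 5, 5), speciation_depth = 5,
#'                     coalescent_depth = 0.5, seed = 1)
simulate_tree <- function(n_species, tips_per_species, speciation_depth,
                          coalescent_depth, seed, species_names = NULL) {
  n_species <- check_count(n_species, "n_species")
  tips_per_species <- rep_len(as.integer(tips_per_species), n_species)
  if (any(tips_per_species < 1L)) abort("`tips_per_species` must all be >= 1")
  if (!is.numeric(speciation_depth) || speciation_depth <= 0) {
    abort("`speciation_depth` must be positive")
  }
  if (!is.numeric(coalescent_depth) || coalescent_depth <= 0 ||
      coalescent_depth >= speciation_depth) {
    abort("`coalescent_depth` must lie in (0, speciation_depth)")
  }
  if (is.null(species_names)) species_names <- paste0("sp", seq_len(n_species))

  with_seed(seed, {
    # species subtrees: rescaled coalescents (height drawn in
    # [coalescent_depth/2, coalescent_depth], clamped well below the
    # shallowest possible species split so stem branches stay positive)
    cap <- if (n_species > 1L) 0.45 * speciation_depth else coalescent_depth
    sub <- vector("list", n_species)
    for (k in seq_len(n_species)) {
      nk <- tips_per_species[k]
      labs <- sprintf("%s_tip%d", species_names[k], seq_len(nk))
      if (nk == 1L) {
        sub[[k]] <- list(newick = labs, height = 0)
      } else {
        tr <- ape::rcoal(nk, tip.label = labs)
        h <- max(ape::node.depth.edgelength(tr))
        target <- min(coalescent_depth * runif(1L, 0.5, 1), cap)
        tr$edge.length <- tr$edge.length * (target / h)
        nwk <- ape::write.tree(tr)
        sub[[k]] <- list(newick = sub(";$", "", nwk), height = target)
      }
    }
    if (n_species == 1L) {
      out <- ape::read.tree(text = paste0(sub[[1L]]$newick, ";"))
    } else {
      # Yule spacings mapped into [speciation_depth/2, speciation_depth];
      # the deepest split is the root at exactly speciation_depth
      depths <- speciation_depth
      if (n_species > 2L) {
        w <- rexp(n_species - 2L, rate = 2:(n_species - 1L))
        cw <- cumsum(w) / (sum(w) + rexp(1L, rate = n_species))
        depths <- c(depths, speciation_depth * (1 - 0.5 * cw))
      }
      depths <- sort(depths) # increasing; merge shallow first, root last
      clusters <- sub
      for (d in depths) {
        pick <- sample.int(length(clusters), 2L)
        a <- clusters[[pick[1L]]]
        b <- clusters[[pick[2L]]]
        merged <- list(
          newick = sprintf(
            "(%s:%.12g,%s:%.12g)", a$newick, d - a$height,
            b$newick, d - b$height
          ),
          height = d
        )
        clusters <- c(clusters[-pick], list(merged))
      }
      out <- ape::read.tree(text = paste0(clusters[[1L]]$newick, ";"))
    }
    attr(out, "species_map") <- tibble(
      tip = out$tip.label,
      species = sub("_tip[0-9]+$", "", out$tip.label)
    )
    attr(out, "seed") <- seed
    out
  })
}

#' Node heights of an ultrametric tree
#'
#' @param tree An [ape::phylo] rooted tree.
#' @param tol Relative tolerance (times root height) for the ultrametricity
#'   check.
#' @return Numeric vector of heights (time before present) indexed by node
#'   number (tips first, then internal nodes).
#' @export
node_heights <- function(tree, tol = 1e-6) {
  stopifnot(inherits(tree, "phylo"))
  depth <- ape::node.depth.edgelength(tree)
  n_tip <- length(tree$tip.label)
  root_h <- max(depth[seq_len(n_tip)])
  if (root_h > 0 && diff(range(depth[seq_len(n_tip)])) > tol * root_h) {
    abort("tree is not ultrametric: tips are not contemporaneous")
  }
  h <- root_h - depth
  h[seq_len(n_tip)] <- 0
  h
}

#' Test monophyly of a tip set by tree traversal
#'
#' @param tree An [ape::phylo] rooted tree.
#' @param tips Character vector of tip labels (or logical/integer index).
#' @return TRUE if the smallest clade containing `tips` contains no other
#'   tips.
#' @export
is_monophyletic_group <- function(tree, tips) {
  idx <- tip_indices(tree, tips)
  cnt <- clade_tip_counts(tree, idx)
  n <- length(idx)
  n_tip <- length(tree$tip.label)
  # MRCA = shallowest node containing all group tips
  full <- which(cnt == n) + n_tip
  h <- node_heights(tree)
  mrca <- full[which.min(h[full])]
  sum(clade_members(tree, mrca)) == n
}

# internal: resolve tip specification to integer indices
tip_indices <- function(tree, tips) {
  if (is.character(tips)) {
    idx <- match(tips, tree$tip.label)
    if (anyNA(idx)) abort("unknown tip labels")
  } else if (is.logical(tips)) {
    idx <- which(tips)
  } else {
    idx <- as.integer(tips)
  }
  unique(idx)
}

# internal: number of group tips below each internal node (postorder pass)
clade_tip_counts <- function(tree, tip_idx) {
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  cnt <- numeric(n_tip + n_node)
  cnt[tip_idx] <- 1
  eo <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(eo$edge))) {
    cnt[eo$edge[e, 1L]] <- cnt[eo$edge[e, 1L]] + cnt[eo$edge[e, 2L]]
  }
  cnt[(n_tip + 1L):(n_tip + n_node)]
}

# internal: logical vector over tips, TRUE if descended from `node`
clade_members <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  below <- logical(n_tip + tree$Nnode)
  below[node] <- TRUE
  eo <- ape::reorder.phylo(tree, "postorder")
  # walk edges root-ward ordering reversed = preorder
  for (e in rev(seq_len(nrow(eo$edge)))) {
    if (below[eo$edge[e, 1L]]) below[eo$edge[e, 2L]] <- TRUE
  }
  below[seq_len(n_tip)]
}
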