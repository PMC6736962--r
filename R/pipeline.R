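# Orchestration: run the full delimitation analysis on synthetic (or
# user-supplied) inputs and summarize cross-method concordance.

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement computed from the contingency table of two
#' partitions of the same individuals; 1 for identical partitions, expected
#' value 0 for independent random partitions.
#'
#' @param p1,p2 Partitions: `eel_partition` objects, data frames with
#'   columns `individual`/`tip` and `cluster`, or named vectors of cluster
#'   labels.
#' @return Adjusted Rand index in `[-1, 1]`.
#' @export
partition_agreement <- function(p1, p2) {
  a <- as_partition_vector(p1)
  b <- as_partition_vector(p2)
  if (!setequal(names(a), names(b))) {
    abort("partitions cover different individual sets")
  }
  b <- b[names(a)]
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(as.vector(tab))
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  max_index <- (si + sj) / 2
  if (max_index == expected) return(1) # both partitions trivial and equal
  (sij - expected) / (max_index - expected)
}

# internal: coerce partition-ish input to a named cluster vector
as_partition_vector <- function(p) {
  if (is.data.frame(p)) {
    idcol <- intersect(c("individual", "tip", "id"), names(p))[1L]
    if (is.na(idcol) || !"cluster" %in% names(p)) {
      abort("partition data frame needs an individual/tip/id and a cluster column")
    }
    return(setNames(p$cluster, p[[idcol]]))
  }
  if (is.null(names(p))) abort("partition vector must be named")
  p
}

# internal: parse a flat key = value config file
read_pipeline_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) abort(sprintf("cannot parse config line: '%s'", lines[bad][1L]))
  vals <- lapply(kv, function(x) {
    v <- x[[2L]]
    if (tolower(v) %in% c("true", "false")) {
      return(as.logical(toupper(v)))
    }
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  setNames(vals, vapply(kv, `[[`, character(1), 1L))
}

#' Run the integrative delimitation pipeline
#'
#' Executes the enabled stages in dependency order on a synthetic preset:
#' alignment simulation, K2P distances, barcode-gap partition, diagnostic
#' sites, tree simulation with GMYC and GSI, the EOD wavelet chain, and the
#' niche MANOVA; writes all intermediate artifacts and a structured
#' concordance report to `out_dir`, and states the consensus lineage count
#' (simple majority over enabled delimitation methods, ties unresolved).
#'
#' @param config Either a path to a flat `key = value` text file or a named
#'   list. Recognized keys: `seed` (default 1), `out_dir` (default a fresh
#'   temporary directory), `preset` (only `"electrophorus"`), and stage
#'   toggles `distances`, `gap_partition`, `diagnostics`, `gmyc`, `gsi`,
#'   `eod`, `manova` (all TRUE by default).
#' @return An object of class `concordance_report`.
#' @export
#' @examples
#' \donttest{
#' rep <- run_pipeline(list(seed = 1, eod = FALSE))
#' rep$consensus_k
#' }
run_pipeline <- function(config = list()) {
  cfg <- if (is.character(config)) read_pipeline_config(config) else config
  get_cfg <- function(key, default) if (!is.null(cfg[[key]])) cfg[[key]] else default
  seed <- as.integer(get_cfg("seed", 1L))
  out_dir <- get_cfg("out_dir", file.path(tempdir(), sprintf("eeldelim_run_%d", seed)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  preset_name <- get_cfg("preset", "electrophorus")
  if (!identical(preset_name, "electrophorus")) {
    abort("only the 'electrophorus' preset is built in")
  }
  stages <- c("distances", "gap_partition", "diagnostics", "gmyc", "gsi", "eod", "manova")
  enabled <- vapply(stages, function(s) isTRUE(get_cfg(s, TRUE)), logical(1))
  names(enabled) <- stages
  log_path <- file.path(out_dir, "pipeline.log")
  log_lines <- c(
    sprintf("seed = %d", seed),
    sprintf("preset = %s", preset_name),
    sprintf("%s = %s", stages, tolower(as.character(enabled)))
  )

  partitions <- list()
  evidence <- list()
  artifacts <- character()
  report <- list(seed = seed, preset = preset_name, stages = as.list(enabled))

  if (!any(enabled)) {
    report$consensus_k <- NA_integer_
    report$note <- "all stages disabled"
    writeLines(log_lines, log_path)
    return(new_concordance_report(report, partitions, tibble(), out_dir))
  }

  preset <- preset_electrophorus()
  truth <- NULL

  needs_aln <- any(enabled[c("distances", "gap_partition", "diagnostics")])
  if (needs_aln) {
    aln <- simulate_alignment(preset, seed = seed)
    fasta <- file.path(out_dir, "alignment.fasta")
    write_alignment_fasta(aln, fasta)
    artifacts <- c(artifacts, fasta)
    tags <- alignment_tags(aln)
    truth <- tags[!tags$is_outgroup, c("individual", "lineage")]
  }

  if (enabled[["distances"]] || enabled[["gap_partition"]]) {
    ingroup <- rownames(aln)[attr(aln, "lineage") != "outgroup"]
    dm <- distance_matrix(unclass(aln)[ingroup, , drop = FALSE])
    dm$lineage <- attr(aln, "lineage")[ingroup]
    if (enabled[["distances"]]) {
      dpath <- file.path(out_dir, "distances.csv")
      write_distances(dm, dpath)
      artifacts <- c(artifacts, dpath)
      div <- group_divergences(dm)
      utils::write.csv(div, file.path(out_dir, "divergences.csv"), row.names = FALSE)
      evidence$divergences <- div
    }
    if (enabled[["gap_partition"]]) {
      part <- barcode_gap_partition(dm)
      utils::write.csv(part, file.path(out_dir, "gap_partition.csv"), row.names = FALSE)
      partitions$barcode_gap <- part
    }
  }

  if (enabled[["diagnostics"]]) {
    diag_tabs <- lapply(preset$lineage_names, function(ln) diagnostic_sites(aln, ln))
    diag_all <- dplyr::bind_rows(diag_tabs)
    utils::write.csv(diag_all, file.path(out_dir, "diagnostic_sites.csv"), row.names = FALSE)
    evidence$diagnostic_sites <- dplyr::count(diag_all, .data$lineage, name = "n_sites")
  }

  if (enabled[["gmyc"]] || enabled[["gsi"]]) {
    # deep species splits relative to within-species coalescents, mirroring
    # the study's ~20-300x between/within divergence ratios
    tree <- simulate_tree(
      preset$n_lineages, preset$n_per_lineage,
      speciation_depth = 5, coalescent_depth = 0.1,
      seed = seed, species_names = preset$lineage_names
    )
    tpath <- file.path(out_dir, "tree.nwk")
    ape::write.tree(tree, tpath)
    artifacts <- c(artifacts, tpath)
    smap <- attr(tree, "species_map")
    if (enabled[["gmyc"]]) {
      fit <- gmyc_fit(tree)
      jsonlite::write_json(
        glance(fit), file.path(out_dir, "gmyc.json"),
        auto_unbox = TRUE, digits = NA
      )
      partitions$gmyc <- tibble(
        individual = fit$clusters$tip, cluster = fit$clusters$cluster
      )
      evidence$gmyc <- glance(fit)
    }
    if (enabled[["gsi"]]) {
      gs <- lapply(preset$lineage_names, function(sp) {
        res <- gsi_pvalue(tree, smap$tip[smap$species == sp],
          n_perm = 1000L, seed = seed
        )
        dplyr::bind_cols(tibble(lineage = sp), res)
      })
      gs <- dplyr::bind_rows(gs)
      utils::write.csv(gs, file.path(out_dir, "gsi.csv"), row.names = FALSE)
      evidence$gsi <- gs
    }
  }

  if (enabled[["eod"]]) {
    # high-SNR direct-digitizer recordings at the published mean durations
    durations <- c(electricus = 2.11, voltai = 1.72, varii = 1.51)
    recs <- unlist(lapply(names(durations), function(sp) {
      simulate_eod(
        eod_template(sp, durations[[sp]], noise_sd = 0.002),
        n = 5L, seed = seed + match(sp, names(durations))
      )
    }), recursive = FALSE)
    fmat <- eod_feature_matrix(recs)
    red <- anova_reduce(fmat, k = 4L)
    utils::write.csv(red$reduced, file.path(out_dir, "eod_features.csv"), row.names = FALSE)
    cl <- nn_cluster(red$reduced)
    k_eod <- best_cut_k(cl)
    eod_part <- cut_eod_clusters(cl, k_eod)
    utils::write.csv(eod_part, file.path(out_dir, "eod_clusters.csv"), row.names = FALSE)
    partitions$eod <- tibble(individual = eod_part$id, cluster = eod_part$cluster)
    evidence$eod_d2 <- mahalanobis_d2(red$reduced)
  }

  if (enabled[["manova"]]) {
    gm <- rbind(
      electricus = c(AMT = 24.5, AMP = 2100, AL = 220, FLA = 3.2),
      voltai = c(AMT = 25.5, AMP = 1850, AL = 310, FLA = 2.6),
      varii = c(AMT = 27.0, AMP = 2500, AL = 60, FLA = 4.4)
    )
    env <- simulate_env_table(
      gm, pooled_sd = c(0.8, 220, 60, 0.7),
      n_per_group = c(29L, 24L, 46L), seed = seed
    )
    utils::write.csv(env, file.path(out_dir, "env_table.csv"), row.names = FALSE)
    mv <- pillai_manova(env)
    jsonlite::write_json(
      glance(mv), file.path(out_dir, "manova.json"),
      auto_unbox = TRUE, digits = NA
    )
    evidence$manova <- glance(mv)
  }

  # cross-method agreement (methods sharing an individual set) and the
  # consensus lineage count over delimitation methods
  agree <- tibble()
  if (length(partitions) >= 2L) {
    prs <- utils::combn(names(partitions), 2L, simplify = FALSE)
    rows <- lapply(prs, function(pr) {
      a <- partitions[[pr[1L]]]
      b <- partitions[[pr[2L]]]
      ids_a <- as_partition_vector(a)
      ids_b <- as_partition_vector(b)
      if (!setequal(names(ids_a), names(ids_b))) {
        return(tibble(
          method_a = pr[1L], method_b = pr[2L],
          ari = NA_real_, partial = TRUE
        ))
      }
      tibble(
        method_a = pr[1L], method_b = pr[2L],
        ari = partition_agreement(a, b), partial = FALSE
      )
    })
    agree <- dplyr::bind_rows(rows)
  }
  ks <- vapply(partitions, function(p) length(unique(p$cluster)), numeric(1))
  if (length(ks)) {
    tab <- sort(table(ks), decreasing = TRUE)
    report$consensus_k <- if (length(tab) > 1L && tab[1L] == tab[2L]) {
      NA_integer_ # tie: unresolved
    } else {
      as.integer(names(tab)[1L])
    }
    report$method_k <- as.list(ks)
  } else {
    report$consensus_k <- NA_integer_
  }

  out <- new_concordance_report(report, partitions, agree, out_dir,
    evidence = evidence
  )
  jsonlite::write_json(
    list(
      seed = seed, preset = preset_name, stages = as.list(enabled),
      method_k = report$method_k, consensus_k = report$consensus_k,
      agreement = agree
    ),
    file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, na = "null"
  )
  log_lines <- c(
    log_lines,
    sprintf("artifacts = %d", length(artifacts)),
    sprintf("report_hash = %s", rlang::hash(list(report, partitions, agree)))
  )
  writeLines(log_lines, log_path)
  writeLines(format(out), file.path(out_dir, "report.txt"))
  out
}

# internal: pick the dendrogram cut below the largest relative (log-scale)
# merge-height jump (the natural cluster count of a single-linkage tree)
best_cut_k <- function(cl) {
  h <- sort(cl$hclust$height)
  n <- length(h) + 1L
  if (n <= 2L) return(n)
  eps <- max(h) * 0.01 # floor keeps near-zero within-group merges from
  # dominating the log-scale jumps
  jumps <- diff(log(h + eps))
  k <- n - which.max(jumps)
  max(2L, min(k, n - 1L))
}

new_concordance_report <- function(report, partitions, agreement, out_dir,
                                   evidence = list()) {
  structure(
    list(
      seed = report$seed,
      preset = report$preset,
      stages = report$stages,
      partitions = partitions,
      method_k = report$method_k,
      consensus_k = report$consensus_k,
      agreement = agreement,
      evidence = evidence,
      out_dir = out_dir,
      note = report$note
    ),
    class = "concordance_report"
  )
}

#' @export
format.concordance_report <- function(x, ...) {
  lines <- c(
    sprintf("Delimitation concordance report (seed %d, preset %s)", x$seed, x$preset),
    sprintf(
      "  stages: %s",
      paste(names(x$stages)[unlist(x$stages)], collapse = ", ")
    )
  )
  if (length(x$method_k)) {
    lines <- c(lines, sprintf(
      "  lineage counts: %s",
      paste(sprintf("%s = %d", names(x$method_k), unlist(x$method_k)), collapse = ", ")
    ))
  }
  lines <- c(lines, sprintf(
    "  consensus lineages: %s",
    if (is.na(x$consensus_k)) "unresolved" else x$consensus_k
  ))
  if (nrow(x$agreement %||% tibble())) {
    lines <- c(lines, "  pairwise agreement (adjusted Rand):")
    for (i in seq_len(nrow(x$agreement))) {
      r <- x$agreement[i, ]
      lines <- c(lines, sprintf(
        "    %s vs %s: %s", r$method_a, r$method_b,
        if (isTRUE(r$partial)) "partial (different individuals)" else sprintf("%.3f", r$ari)
      ))
    }
  }
  if (!is.null(x$note)) lines <- c(lines, sprintf("  note: %s", x$note))
  lines
}

#' @export
print.concordance_report <- function(x, ...) {
  writeLines(format(x))
  invisible(x)
}
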