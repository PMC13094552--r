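#' Analysis configuration
#'
#' Bundles the tunable knobs shared across stages. Defaults follow the
#' study design: 25\% of each class held out for testing, 1000 permutations
#' for Blomberg's K, 1000 Brownian-motion simulations for the C1 null, and
#' `Suction` as the positive class.
#'
#' @param seed integer seed driving every stochastic stage
#' @param test_fraction held-out fraction per class
#' @param n_perm permutations for the K test
#' @param n_sim BM simulations for the C1 null
#' @param positive_class positive feeding-mode level
#' @param missing_policy `"renormalize"` or `"error"` (see [compute_ssi()])
#' @return list of class `"analysis_config"`
#' @export
analysis_config <- function(seed = 1L, test_fraction = 0.25, n_perm = 1000L,
                            n_sim = 1000L, positive_class = "Suction",
                            missing_policy = "renormalize") {
  stopifnot(test_fraction > 0, test_fraction < 1, n_perm >= 1L, n_sim >= 1L)
  structure(
    list(seed = as.integer(seed), test_fraction = test_fraction,
         n_perm = as.integer(n_perm), n_sim = as.integer(n_sim),
         positive_class = positive_class, missing_policy = missing_policy),
    class = "analysis_config"
  )
}

#' Run the full analysis pipeline
#'
#' Executes the four stages in order on one dataset: (1) SSI computation
#' and ranking; (2) association with feeding mode -- per-character and
#' composite Kruskal-Wallis tests, Blomberg's K with permutation p, and
#' PGLS-vs-OLS fits of score on feeding mode; (3) the classifier battery
#' against the no-information rate; (4) standardized PCA of the skull
#' block, phylomorphospace projection, and the C1 convergence test with the
#' Suction-labelled taxa as the focal set. Stage reports are written as
#' JSON when `out_dir` is given.
#'
#' @param suction a [character_matrix()] of suction-related characters
#' @param labels named `"Suction"`/`"Other"` vector
#' @param tree an `ape::phylo` (pruned/matched to the data if needed); may
#'   be `NULL`, in which case the phylogenetic stages (K, PGLS, C1) are
#'   skipped with a recorded reason
#' @param skull optional skull-shape [character_matrix()]; if `NULL` the
#'   morphospace stage is skipped
#' @param config an [analysis_config()]
#' @param out_dir optional directory for JSON stage reports
#' @return list of class `"pipeline_run"` with elements `config`, `ssi`,
#'   `ranking`, `correlation` (per-variable list of kw/K/ols/pgls),
#'   `battery`, `morphospace` (var_fraction, scores), `convergence`,
#'   `skipped` (named reasons), `provenance`
#' @export
run_pipeline <- function(suction, labels, tree = NULL, skull = NULL,
                         config = analysis_config(), out_dir = NULL) {
  stopifnot(inherits(suction, "character_matrix"))
  skipped <- list()
  t0 <- Sys.time()

  ssi <- compute_ssi(suction, policy = config$missing_policy)
  ranking <- rank_taxa(ssi)

  if (!is.null(tree)) {
    pm <- prune_and_match(tree, taxa(suction))
    tree <- pm$tree
  }

  # stage 2: association of each score variable with feeding mode
  vars <- c(as.list(characters(suction)),
            list("CharMean", "AdjustedSSI"))
  get_values <- function(v) {
    if (v == "CharMean") {
      stats::setNames(ssi$char_mean, ssi$taxon)
    } else if (v == "AdjustedSSI") {
      stats::setNames(ssi$adjusted_ssi, ssi$taxon)
    } else {
      suction$scores[, v]
    }
  }
  lab_of <- function(nms) {
    labels[match(normalize_taxon(nms), normalize_taxon(names(labels)))]
  }
  correlation <- lapply(vars, function(v) {
    y <- get_values(v)
    grp <- lab_of(names(y))
    out <- list(variable = v, kruskal_wallis = kruskal_wallis(y, grp))
    out$ols <- pgls_fit(y, stats::setNames(grp, names(y)), tree = NULL)
    if (!is.null(tree)) {
      out$blomberg_k <- blomberg_k(tree, y, n_perm = config$n_perm,
                                   seed = config$seed)
      out$pgls <- pgls_fit(y, stats::setNames(grp, names(y)), tree = tree)
    }
    out
  })
  names(correlation) <- unlist(vars)
  if (is.null(tree)) {
    skipped$blomberg_k <- skipped$pgls <- "no tree supplied"
  }

  battery <- run_predictor_battery(suction, labels, ssi_table = ssi,
                                   test_fraction = config$test_fraction,
                                   seed = config$seed)

  morpho <- convergence <- pms <- NULL
  if (!is.null(skull)) {
    morpho <- standardized_pca(skull)
    if (!is.null(tree)) {
      pms <- phylomorphospace(tree, morpho)
      focal <- names(labels)[labels == config$positive_class]
      focal <- intersect(normalize_taxon(focal), normalize_taxon(tree$tip.label))
      convergence <- c1_group_test(tree, morpho, focal,
                                   n_sim = config$n_sim, seed = config$seed)
    } else {
      skipped$convergence <- "no tree supplied"
    }
  } else {
    skipped$morphospace <- "no skull matrix supplied"
  }

  run <- structure(
    list(config = config, ssi = ssi, ranking = ranking,
         correlation = correlation, battery = battery,
         morphospace = morpho, phylomorphospace = pms,
         convergence = convergence, skipped = skipped,
         provenance = list(
           n_taxa = nrow(suction$scores),
           n_characters = ncol(suction$scores),
           n_skull = if (!is.null(skull)) ncol(skull$scores) else 0L,
           seed = config$seed,
           package_version = as.character(utils::packageVersion("suctionmorph")),
           elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
         )),
    class = "pipeline_run"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report(ssi, file.path(out_dir, "ssi.json"))
    write_report(correlation, file.path(out_dir, "correlation.json"))
    write_report(list(table = battery$table, nir = battery$nir,
                      seed = battery$seed),
                 file.path(out_dir, "battery.json"))
    if (!is.null(morpho)) {
      write_report(list(var_fraction = morpho$var_fraction,
                        dropped = morpho$dropped),
                   file.path(out_dir, "morphospace.json"))
    }
    if (!is.null(convergence)) {
      write_report(convergence, file.path(out_dir, "convergence.json"))
    }
    write_report(c(run$provenance, list(skipped = skipped)),
                 file.path(out_dir, "run_info.json"))
  }
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("pipeline run\n")
  cat(sprintf("  taxa: %d; top SSI: %s (%.3f)\n", x$provenance$n_taxa,
              x$ranking[1L], max(x$ssi$char_mean)))
  cat(sprintf("  battery: NIR %.4f, best accuracy %.4f\n", x$battery$nir,
              max(x$battery$table$accuracy)))
  if (!is.null(x$morphospace)) {
    cat(sprintf("  morphospace: PC1 %.1f%%, PC2 %.1f%%\n",
                100 * x$morphospace$var_fraction[1L],
                100 * x$morphospace$var_fraction[2L]))
  }
  if (!is.null(x$convergence)) {
    cat(sprintf("  convergence: mean C1 %.4f, p %.3f\n",
                x$convergence$mean_c1, x$convergence$p_value))
  }
  if (length(x$skipped)) {
    cat("  skipped:", paste(names(x$skipped), unlist(x$skipped),
                            sep = ": ", collapse = "; "), "\n")
  }
  invisible(x)
}
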