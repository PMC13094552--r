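.suction_chars <- c(
  "blunt_wide_rostrum", "reduced_dentition", "dental_wear",
  "non_occluding_teeth_jaws", "robust_tongue_hyoid", "specialized_palate",
  "weak_jaw_adductors", "long_mandibular_symphysis", "round_mouth",
  "throat_grooves"
)
.soft_tissue_chars <- c("round_mouth", "throat_grooves")
.binary_chars <- "throat_grooves"

#' Configuration for the synthetic odontocete dataset
#'
#' Defaults emulate the structure of the study system: 68 taxa, 10
#' suction-related ordinal characters on the 0--3 scale (two soft-tissue,
#' one strictly binary), a 25-character skull-shape block, and 5 mutually
#' non-nested specialist clades (mirroring the independently suction-feeding
#' lineages: beaked whales, sperm whales, monodontids, pilot whales,
#' Risso's dolphin). Ordinal scores arise from a latent Brownian-motion
#' liability cut at fixed thresholds; specialist-clade tips receive a
#' latent-mean shift `delta` (in units of the BM tip standard deviation) on
#' the suction characters, attenuated per character so that weak predictors
#' exist; skull characters evolve with no shift.
#'
#' @param n_taxa number of tips (default 68)
#' @param birth_rate Yule speciation rate (default 1; affects time scale
#'   only)
#' @param n_specialist_clades number of planted specialist clades (default 5)
#' @param delta latent-mean shift for specialists, in tip-SD units
#'   (default 3: a strong, cleanly separating effect)
#' @param attenuation per-character multiplier on `delta` (length 10; the
#'   defaults make the blunt/wide rostrum a near-useless predictor and the
#'   symphysis and round mouth mediocre ones)
#' @param thresholds_q liability quantiles cutting scores 0|1|2|3 for the
#'   suction characters; the low-skewed default \{0.4, 0.65, 0.85\} makes
#'   most non-specialist taxa score 0--1
#' @param skull_thresholds_q liability quantiles for the skull block
#' @param bm_rate Brownian-motion rate of the liabilities
#' @param n_skull number of skull-shape characters (default 25)
#' @param clade_size_range allowed specialist-clade size as a fraction of
#'   tips (default 1--25\%; single tips count as degenerate clades)
#' @param seed integer seed used by [generate_dataset()]
#' @return a list of class `"synth_config"`
#' @export
synth_config <- function(n_taxa = 68L, birth_rate = 1, n_specialist_clades = 5L,
                         delta = 3,
                         attenuation = c(0.15, 1, 0.8, 1, 0.8, 1, 1, 0.5,
                                         0.4, 1),
                         thresholds_q = c(0.4, 0.65, 0.85),
                         skull_thresholds_q = c(0.25, 0.5, 0.75),
                         bm_rate = 1, n_skull = 25L,
                         clade_size_range = c(0.01, 0.25), seed = 1L) {
  stopifnot(n_taxa >= 4L, delta >= 0, n_specialist_clades >= 1L,
            length(attenuation) == 10L,
            !is.unsorted(thresholds_q, strictly = TRUE),
            all(thresholds_q > 0), all(thresholds_q < 1))
  structure(
    list(n_taxa = as.integer(n_taxa), birth_rate = birth_rate,
         n_specialist_clades = as.integer(n_specialist_clades), delta = delta,
         attenuation = attenuation, thresholds_q = thresholds_q,
         skull_thresholds_q = skull_thresholds_q, bm_rate = bm_rate,
         n_skull = as.integer(n_skull), clade_size_range = clade_size_range,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

#' Simulate a Yule (pure-birth) tree
#'
#' Wrapper around [phytools::pbtree()]: exponential waiting times, no
#' extinction, ultrametric, tips labelled `t1 ... tn`.
#'
#' @param n_taxa number of tips (>= 4)
#' @param birth_rate speciation rate
#' @param seed optional integer seed
#' @return an `ape::phylo`
#' @export
simulate_yule_tree <- function(n_taxa, birth_rate = 1, seed = NULL) {
  stopifnot(n_taxa >= 4L)
  if (!is.null(seed)) set.seed(seed)
  phytools::pbtree(b = birth_rate, d = 0, n = n_taxa, quiet = TRUE)
}

.clade_tip_sets <- function(tree) {
  n <- ape::Ntip(tree)
  sets <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) sets[[i]] <- i
  # edges in ape cladewise order: process children before parents via reverse
  for (e in rev(seq_len(nrow(tree$edge)))) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

#' Plant mutually non-nested specialist clades on a tree
#'
#' Randomly selects `n_clades` clades (internal nodes, or single tips as
#' degenerate clades) with disjoint tip sets, each within the allowed size
#' range. These are the lineages in which suction specialization is planted.
#'
#' @param tree an `ape::phylo`
#' @param n_clades number of clades
#' @param size_range clade size as a fraction of tips, `c(min, max)`
#' @param seed optional integer seed
#' @return list with `tips` (character vector of all specialist tips) and
#'   `clades` (list of per-clade tip-label vectors)
#' @export
plant_specialist_clades <- function(tree, n_clades, size_range = c(0.01, 0.25),
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- ape::Ntip(tree)
  lo <- max(1L, ceiling(size_range[1L] * n))
  hi <- max(lo, floor(size_range[2L] * n))
  sets <- .clade_tip_sets(tree)
  cand <- which(lengths(sets) >= lo & lengths(sets) <= hi)
  cand <- sample(cand)
  chosen <- list()
  used <- integer(0)
  for (v in cand) {
    if (length(chosen) == n_clades) break
    if (!any(sets[[v]] %in% used)) {
      chosen[[length(chosen) + 1L]] <- sets[[v]]
      used <- c(used, sets[[v]])
    }
  }
  if (length(chosen) < n_clades) {
    stop(sprintf(
      "could only place %d of %d non-nested clades in [%d, %d] tips; request fewer clades",
      length(chosen), n_clades, lo, hi))
  }
  clades <- lapply(chosen, function(ix) tree$tip.label[ix])
  list(tips = unlist(clades), clades = clades)
}

.threshold_scores <- function(L, thresholds) {
  sc <- matrix(findInterval(L, thresholds), nrow(L), ncol(L),
               dimnames = dimnames(L))
  sc
}

#' Simulate the suction-related character block and feeding-mode labels
#'
#' Each of the 10 characters is a latent liability evolving by Brownian
#' motion on the tree; specialist-clade tips get `delta * attenuation[j]`
#' tip-SDs added to their liabilities; liabilities are cut at the
#' `thresholds_q` quantiles of the tip distribution into scores 0--3. The
#' throat-grooves character is strictly binary: 3 where the liability
#' exceeds the top threshold, else 0. Labels are `Suction` exactly for
#' specialist-clade members.
#'
#' @param tree an `ape::phylo`
#' @param config a [synth_config()]
#' @param specialist_tips optional character vector of specialist tips; if
#'   `NULL`, clades are planted via [plant_specialist_clades()]
#' @param seed optional integer seed
#' @return list: `matrix` (a [character_matrix()]), `labels`,
#'   `specialist_tips`
#' @export
simulate_suction_characters <- function(tree, config = synth_config(),
                                        specialist_tips = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(specialist_tips)) {
    specialist_tips <- plant_specialist_clades(
      tree, config$n_specialist_clades, config$clade_size_range)$tips
  }
  depth <- max(ape::node.depth.edgelength(tree))
  tip_sd <- sqrt(config$bm_rate * depth)
  k <- length(.suction_chars)
  L <- simulate_bm(tree, diag(k) * config$bm_rate)[[1L]]
  colnames(L) <- .suction_chars
  spec <- rownames(L) %in% specialist_tips
  shift <- config$delta * tip_sd * config$attenuation
  L[spec, ] <- sweep(L[spec, , drop = FALSE], 2L, shift, `+`)
  thr <- stats::qnorm(config$thresholds_q) * tip_sd
  sc <- .threshold_scores(L, thr)
  bin <- .binary_chars
  sc[, bin] <- ifelse(L[, bin] > thr[3L], 3, 0)
  sc[, setdiff(.suction_chars, bin)][] <-
    pmin(pmax(sc[, setdiff(.suction_chars, bin)], 0), 3)
  cm <- character_matrix(
    sc,
    char_class = ifelse(.suction_chars %in% .soft_tissue_chars,
                        "soft_tissue", "osteo_dental"),
    binary = .suction_chars %in% bin
  )
  labels <- stats::setNames(
    ifelse(rownames(sc) %in% specialist_tips, "Suction", "Other"),
    rownames(sc)
  )
  list(matrix = cm, labels = labels, specialist_tips = specialist_tips)
}

#' Simulate the skull-shape character block
#'
#' 25 ordinal characters from thresholded Brownian-motion liabilities with
#' no specialist shift: skull shape carries phylogenetic signal but no
#' suction-linked convergence, the null pattern against which the C1
#' machinery is calibrated.
#'
#' @inheritParams simulate_suction_characters
#' @return a [character_matrix()]
#' @export
simulate_skull_characters <- function(tree, config = synth_config(),
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  depth <- max(ape::node.depth.edgelength(tree))
  tip_sd <- sqrt(config$bm_rate * depth)
  k <- config$n_skull
  L <- simulate_bm(tree, diag(k) * config$bm_rate)[[1L]]
  colnames(L) <- sprintf("skull_%02d", seq_len(k))
  thr <- stats::qnorm(config$skull_thresholds_q) * tip_sd
  character_matrix(.threshold_scores(L, thr))
}

#' Generate a complete synthetic dataset
#'
#' Assembles tree, suction-character matrix, labels, skull matrix and a
#' ground-truth record, all reproducible from `config$seed`. If `out_dir`
#' is given, writes `tree.nwk`, `suction_scores.csv`, `skull_scores.csv`,
#' `labels.csv` and `truth.json` there.
#'
#' @param config a [synth_config()]
#' @param out_dir optional output directory
#' @return list of class `"synth_dataset"`: `tree`, `suction` (matrix),
#'   `labels`, `skull`, `truth`
#' @export
generate_dataset <- function(config = synth_config(), out_dir = NULL) {
  set.seed(config$seed)
  tree <- simulate_yule_tree(config$n_taxa, config$birth_rate)
  planted <- plant_specialist_clades(tree, config$n_specialist_clades,
                                     config$clade_size_range)
  suction <- simulate_suction_characters(tree, config,
                                         specialist_tips = planted$tips)
  skull <- simulate_skull_characters(tree, config)
  truth <- list(
    specialist_tips = planted$tips, specialist_clades = planted$clades,
    delta = config$delta, attenuation = config$attenuation,
    thresholds_q = config$thresholds_q, seed = config$seed
  )
  out <- structure(
    list(tree = tree, suction = suction$matrix, labels = suction$labels,
         skull = skull, truth = truth),
    class = "synth_dataset"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    ape::write.tree(tree, file.path(out_dir, "tree.nwk"))
    write_character_matrix(suction$matrix,
                           file.path(out_dir, "suction_scores.csv"))
    write_character_matrix(skull, file.path(out_dir, "skull_scores.csv"))
    write_label_table(suction$labels, file.path(out_dir, "labels.csv"))
    write_report(truth, file.path(out_dir, "truth.json"))
  }
  out
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat(sprintf(
    "synthetic dataset: %d taxa (%d Suction), %d + %d characters, seed %d\n",
    ape::Ntip(x$tree), sum(x$labels == "Suction"), ncol(x$suction$scores),
    ncol(x$skull$scores), x$truth$seed))
  invisible(x)
}
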