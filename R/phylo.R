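#' Parse a Newick tree
#'
#' Thin validating wrapper around [ape::read.tree()]. The tree must be
#' rooted-style Newick with branch lengths on every edge; tip labels must be
#' unique. All downstream Brownian-motion machinery (covariance, ancestral
#' states, simulation) interprets branch lengths as time.
#'
#' @param text a Newick string, e.g. `"((A:1,B:1):1,C:2);"`
#' @return an [ape::phylo] object
#' @export
parse_newick <- function(text) {
  tr <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(tr) || !inherits(tr, "phylo")) {
    stop("malformed Newick string: ", substr(text, 1, 60))
  }
  .validate_tree(tr)
  tr
}

#' @rdname parse_newick
#' @param path path to a Newick file containing a single tree
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  parse_newick(paste(readLines(path, warn = FALSE), collapse = ""))
}

.validate_tree <- function(tr) {
  if (is.null(tr$edge.length) || anyNA(tr$edge.length)) {
    stop("branch lengths required on every edge")
  }
  if (any(tr$edge.length < 0)) stop("negative branch lengths")
  if (anyDuplicated(tr$tip.label)) stop("duplicate tip labels")
  invisible(tr)
}

#' Prune a tree to the taxa shared with a trait table
#'
#' Matching is on normalized names ([normalize_taxon()]): underscore/space
#' and case differences between tip labels and table names are tolerated.
#' Degree-2 nodes created by pruning are collapsed with branch lengths
#' summed (the [ape::keep.tip()] behaviour), so root-to-tip path lengths of
#' retained tips are preserved.
#'
#' @param tree an `ape::phylo`
#' @param taxa_names character vector of taxon names from the data side
#' @return list with elements `tree` (pruned), `matched` (data frame
#'   tree_tip/taxon), `dropped_tips` (in tree only), `dropped_taxa`
#'   (in data only)
#' @export
prune_and_match <- function(tree, taxa_names) {
  tn <- normalize_taxon(tree$tip.label)
  dn <- normalize_taxon(taxa_names)
  shared <- intersect(tn, dn)
  if (length(shared) < 3L) {
    stop(sprintf(
      "fewer than 3 shared taxa; tree-only: [%s]; data-only: [%s]",
      paste(tree$tip.label[!(tn %in% dn)], collapse = ", "),
      paste(taxa_names[!(dn %in% tn)], collapse = ", ")
    ))
  }
  keep <- tree$tip.label[tn %in% shared]
  pruned <- ape::keep.tip(tree, keep)
  # record the basal path from the old root to the new one as a root edge,
  # so shared ancestry (and hence the BM covariance submatrix) is preserved
  d_full <- ape::node.depth.edgelength(tree)[match(keep[1L], tree$tip.label)]
  d_sub <- ape::node.depth.edgelength(pruned)[match(keep[1L],
                                                    pruned$tip.label)]
  stem <- (d_full - d_sub) +
    (if (is.null(tree$root.edge)) 0 else tree$root.edge)
  if (stem > 1e-12) pruned$root.edge <- stem
  matched <- data.frame(
    tree_tip = keep,
    taxon = taxa_names[match(normalize_taxon(keep), dn)],
    stringsAsFactors = FALSE
  )
  list(
    tree = pruned,
    matched = matched,
    dropped_tips = tree$tip.label[!(tn %in% shared)],
    dropped_taxa = taxa_names[!(dn %in% shared)]
  )
}

#' Brownian-motion covariance matrix of a tree
#'
#' `V[i, j]` is the shared branch length from the root to the most recent
#' common ancestor of tips i and j (the expected trait covariance under
#' Brownian motion); the diagonal holds root-to-tip depths.
#'
#' @param tree an `ape::phylo` with branch lengths
#' @return symmetric positive semi-definite matrix with tip-label dimnames
#' @export
phylo_vcv <- function(tree) {
  .validate_tree(tree)
  V <- ape::vcv.phylo(tree)
  # a root edge is ancestry shared by every tip
  if (!is.null(tree$root.edge)) V <- V + tree$root.edge
  V
}

# Cholesky-based inverse of V with an epsilon fallback for singular V
# (zero-length cherries in published supertrees). eps scales with depth.
.inv_vcv <- function(V, eps = NULL) {
  if (is.null(eps)) eps <- 1e-8 * max(diag(V))
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) ch <- chol(V + eps * diag(nrow(V)))
  chol2inv(ch)
}

# Symmetric PSD square root, tolerant of zero eigenvalues (chol is not)
.psd_sqrt <- function(R, tol = 1e-10) {
  R <- (R + t(R)) / 2
  e <- eigen(R, symmetric = TRUE)
  if (any(e$values < -tol * max(abs(e$values), 1))) {
    stop("rate matrix is not positive semi-definite")
  }
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

# Linear operator A mapping tip values to joint ML ancestral states under BM.
# Minimizing sum over edges of (x_child - x_parent)^2 / length (weighted
# squared-change parsimony, equivalent to the joint BM ML reconstruction) is
# a sparse linear system in the internal-node states: a weighted graph
# Laplacian restricted to internal nodes. anc = A %*% tipY.
.anc_operator <- function(tree, eps = NULL) {
  n <- ape::Ntip(tree)
  m <- tree$Nnode
  el <- tree$edge.length
  if (is.null(eps)) eps <- 1e-8 * max(ape::node.depth.edgelength(tree))
  w <- 1 / pmax(el, eps)
  L <- matrix(0, m, m)
  B <- matrix(0, m, n)
  for (e in seq_along(w)) {
    p <- tree$edge[e, 1L] - n
    ch <- tree$edge[e, 2L]
    L[p, p] <- L[p, p] + w[e]
    if (ch > n) {
      ci <- ch - n
      L[ci, ci] <- L[ci, ci] + w[e]
      L[p, ci] <- L[p, ci] - w[e]
      L[ci, p] <- L[ci, p] - w[e]
    } else {
      B[p, ch] <- B[p, ch] + w[e]
    }
  }
  A <- solve(L, B)
  rownames(A) <- as.character(n + seq_len(m))
  colnames(A) <- tree$tip.label
  A
}

#' Maximum-likelihood ancestral states under Brownian motion
#'
#' Joint ML reconstruction of internal-node states for one or more
#' continuous traits on a rooted, branch-lengthed tree (equivalently,
#' weighted squared-change parsimony). The root estimate equals the GLS
#' phylogenetic mean \eqn{\hat a = (1' V^{-1} y) / (1' V^{-1} 1)}.
#'
#' @param tree an `ape::phylo`
#' @param tip_values named numeric vector, or matrix with taxon rownames
#'   (one column per trait)
#' @return numeric matrix, one row per internal node (rownames are ape node
#'   numbers, root first), one column per trait
#' @export
ancestral_states_bm <- function(tree, tip_values) {
  Y <- .tip_matrix(tree, tip_values)
  A <- .anc_operator(tree)
  A %*% Y
}

.tip_matrix <- function(tree, tip_values) {
  if (is.null(dim(tip_values))) {
    tip_values <- matrix(tip_values, ncol = 1L,
                         dimnames = list(names(tip_values), "trait"))
  }
  nm <- rownames(tip_values)
  if (is.null(nm)) stop("tip values must be named by taxon")
  idx <- match(normalize_taxon(tree$tip.label), normalize_taxon(nm))
  if (anyNA(idx)) {
    stop("no value for tip(s): ",
         paste(tree$tip.label[is.na(idx)], collapse = ", "))
  }
  Y <- tip_values[idx, , drop = FALSE]
  rownames(Y) <- tree$tip.label
  Y
}

#' Estimate the Brownian-motion evolutionary rate matrix
#'
#' Multivariate BM rate estimator on phylogenetic GLS residuals:
#' \eqn{\hat R = (Y - 1\hat a')' V^{-1} (Y - 1\hat a') / (n - 1)}, with
#' \eqn{\hat a} the GLS phylogenetic mean per trait. For a single trait on a
#' star tree with equal depths c this reduces to the sample variance / c.
#'
#' @inheritParams ancestral_states_bm
#' @return k x k symmetric PSD matrix (k = number of traits)
#' @export
estimate_rate_matrix <- function(tree, tip_values) {
  Y <- .tip_matrix(tree, tip_values)
  n <- nrow(Y)
  if (n <= ncol(Y)) {
    warning("fewer tips than traits + 1; rate matrix estimate is rank-deficient")
  }
  V <- phylo_vcv(tree)
  iV <- .inv_vcv(V)
  one <- rep(1, n)
  a <- as.numeric(crossprod(one, iV %*% Y)) / sum(iV)
  Yc <- sweep(Y, 2L, a)
  R <- crossprod(Yc, iV %*% Yc) / (n - 1)
  (R + t(R)) / 2
}

#' Phylogenetic GLS mean of tip values
#' @inheritParams ancestral_states_bm
#' @return numeric vector, one entry per trait
#' @export
phylo_mean <- function(tree, tip_values) {
  Y <- .tip_matrix(tree, tip_values)
  iV <- .inv_vcv(phylo_vcv(tree))
  as.numeric(crossprod(rep(1, nrow(Y)), iV %*% Y)) / sum(iV)
}

#' Simulate Brownian-motion trait evolution on a tree
#'
#' Each replicate draws tip values from the matrix normal with mean
#' `root_state` and covariance `kronecker(R, V)`: rows (tips) covary as the
#' tree dictates, columns (traits) as the rate matrix dictates.
#'
#' @param tree an `ape::phylo`
#' @param rate scalar rate (one trait) or k x k PSD rate matrix
#' @param root_state numeric vector of length k (default zeros)
#' @param n_reps number of replicates
#' @param seed optional integer seed; replicates are drawn sequentially from
#'   the one seeded stream, so results are reproducible given the seed
#' @return list of `n_reps` numeric matrices (tips x traits, taxon rownames)
#' @export
simulate_bm <- function(tree, rate, root_state = NULL, n_reps = 1L,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(dim(rate))) rate <- diag(length(rate)) * rate
  k <- nrow(rate)
  if (is.null(root_state)) root_state <- rep(0, k)
  stopifnot(length(root_state) == k)
  V <- phylo_vcv(tree)
  n <- nrow(V)
  eps <- 1e-8 * max(diag(V))
  Lv <- t(tryCatch(chol(V), error = function(e) chol(V + eps * diag(n))))
  Mr <- .psd_sqrt(rate)
  lapply(seq_len(n_reps), function(r) {
    Z <- matrix(stats::rnorm(n * k), n, k)
    Y <- Lv %*% Z %*% Mr
    Y <- sweep(Y, 2L, root_state, `+`)
    dimnames(Y) <- list(tree$tip.label, colnames(rate))
    Y
  })
}
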