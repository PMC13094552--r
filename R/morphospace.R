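#' Standardized principal component analysis of a skull-shape matrix
#'
#' Ordinal skull-shape characters are treated as numeric, z-scored per
#' character (mean 0, SD 1, n - 1 denominator), and decomposed with
#' [stats::prcomp()]. Zero-variance characters are dropped with a warning
#' (they carry no shape information and cannot be standardized). Axis signs
#' are fixed deterministically: within each component the loading of largest
#' magnitude is made positive, so reports are reproducible across platforms.
#'
#' @param x a [character_matrix()] (or plain numeric matrix with taxon
#'   rownames)
#' @param impute_mean if `TRUE`, missing scores are replaced by the character
#'   mean before standardization; by default missing values are an error
#' @return list of class `"morphospace"`: `scores` (taxa x axes), `loadings`
#'   (characters x axes), `var_fraction`, `sdev`, `center`, `scale`,
#'   `dropped` (zero-variance character names)
#' @export
standardized_pca <- function(x, impute_mean = FALSE) {
  S <- if (inherits(x, "character_matrix")) x$scores else as.matrix(x)
  if (anyNA(S)) {
    if (!impute_mean) {
      bad <- which(is.na(S), arr.ind = TRUE)[1L, ]
      stop(sprintf(
        "missing value (taxon '%s', character '%s'); set impute_mean = TRUE to mean-impute",
        rownames(S)[bad[1L]], colnames(S)[bad[2L]]))
    }
    for (j in seq_len(ncol(S))) {
      S[is.na(S[, j]), j] <- mean(S[, j], na.rm = TRUE)
    }
  }
  v <- apply(S, 2L, stats::var)
  dropped <- colnames(S)[v == 0]
  if (length(dropped) > 0L) {
    warning("dropping zero-variance character(s): ",
            paste(dropped, collapse = ", "))
    S <- S[, v > 0, drop = FALSE]
  }
  if (ncol(S) < 2L) stop("need at least 2 characters with nonzero variance")
  pr <- stats::prcomp(S, center = TRUE, scale. = TRUE)
  for (j in seq_len(ncol(pr$rotation))) {
    i_max <- which.max(abs(pr$rotation[, j]))
    if (pr$rotation[i_max, j] < 0) {
      pr$rotation[, j] <- -pr$rotation[, j]
      pr$x[, j] <- -pr$x[, j]
    }
  }
  structure(
    list(scores = pr$x, loadings = pr$rotation,
         var_fraction = pr$sdev^2 / sum(pr$sdev^2), sdev = pr$sdev,
         center = pr$center, scale = pr$scale, dropped = dropped),
    class = "morphospace"
  )
}

#' @export
print.morphospace <- function(x, ...) {
  vf <- x$var_fraction
  cat(sprintf("morphospace: %d taxa, %d axes; PC1 %.1f%%, PC2 %.1f%%\n",
              nrow(x$scores), length(vf), 100 * vf[1L],
              if (length(vf) > 1L) 100 * vf[2L] else NA))
  invisible(x)
}

.score_matrix <- function(scores) {
  if (inherits(scores, "morphospace")) scores$scores else as.matrix(scores)
}

#' Phylomorphospace projection of a tree into PC space
#'
#' Computes internal-node coordinates on the first two morphospace axes by
#' maximum-likelihood Brownian-motion ancestral reconstruction
#' ([ancestral_states_bm()]) and returns tip/node coordinates plus the
#' parent-child edge segments needed to draw the tree through the
#' morphospace.
#'
#' @param tree an `ape::phylo`
#' @param scores a `"morphospace"` object or taxa x axes matrix (the first
#'   two axes are used)
#' @return list of class `"phylomorphospace"`: `tip_coords`, `node_coords`,
#'   `edges` (data frame parent, child, x0, y0, x1, y1)
#' @export
phylomorphospace <- function(tree, scores) {
  Y <- .tip_matrix(tree, .score_matrix(scores)[, 1:2, drop = FALSE])
  anc <- ancestral_states_bm(tree, Y)
  n <- ape::Ntip(tree)
  coord <- function(node) {
    if (node <= n) Y[node, ] else anc[as.character(node), ]
  }
  eg <- t(apply(tree$edge, 1L, function(e) c(coord(e[1L]), coord(e[2L]))))
  edges <- data.frame(
    parent = tree$edge[, 1L], child = tree$edge[, 2L],
    x0 = eg[, 1L], y0 = eg[, 2L], x1 = eg[, 3L], y1 = eg[, 4L]
  )
  structure(
    list(tip_coords = Y, node_coords = anc, edges = edges),
    class = "phylomorphospace"
  )
}

#' @export
#' @rdname phylomorphospace
#' @param x a `"phylomorphospace"` object
#' @param col tip point colour(s)
#' @param ... passed to [graphics::plot()]
plot.phylomorphospace <- function(x, col = "steelblue", ...) {
  xl <- range(c(x$tip_coords[, 1L], x$node_coords[, 1L]))
  yl <- range(c(x$tip_coords[, 2L], x$node_coords[, 2L]))
  graphics::plot(NA, xlim = xl, ylim = yl, xlab = "PC1", ylab = "PC2", ...)
  graphics::segments(x$edges$x0, x$edges$y0, x$edges$x1, x$edges$y1,
                     col = "grey60")
  graphics::points(x$node_coords, pch = 16, cex = 0.5, col = "grey40")
  graphics::points(x$tip_coords, pch = 21, bg = col)
  invisible(x)
}

# Per-pair lineage bookkeeping: internal-node ids (as character, matching
# ancestral-state rownames) on the path from the MRCA to each tip.
.c1_pairs_info <- function(tree, focal_tips) {
  n <- ape::Ntip(tree)
  idx <- match(focal_tips, tree$tip.label)
  pairs <- utils::combn(seq_along(idx), 2L)
  apply(pairs, 2L, function(pr) {
    ia <- idx[pr[1L]]; ib <- idx[pr[2L]]
    mrca <- ape::getMRCA(tree, c(ia, ib))
    pa <- ape::nodepath(tree, mrca, ia)
    pb <- ape::nodepath(tree, mrca, ib)
    list(tip_a = tree$tip.label[ia], tip_b = tree$tip.label[ib],
         ia = ia, ib = ib,
         nodes_a = as.character(pa[pa > n]), nodes_b = as.character(pb[pb > n]))
  })
}

.cross_max_dist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
  sqrt(max(pmax(d2, 0)))
}

.c1_eval <- function(tipY, ancY, info, include_tips = TRUE) {
  dtip <- sqrt(sum((tipY[info$ia, ] - tipY[info$ib, ])^2))
  SA <- ancY[info$nodes_a, , drop = FALSE]
  SB <- ancY[info$nodes_b, , drop = FALSE]
  if (include_tips) {
    SA <- rbind(SA, tipY[info$ia, , drop = FALSE])
    SB <- rbind(SB, tipY[info$ib, , drop = FALSE])
  }
  dmax <- .cross_max_dist(SA, SB)
  c1 <- if (dmax > 0) 1 - dtip / dmax else 0
  c(C1 = c1, Dtip = dtip, Dmax = dmax)
}

#' Convergence metric C1 for a pair of tips
#'
#' C1 = 1 - Dtip / Dmax, where Dtip is the Euclidean distance between the
#' two tips over all morphospace axes and Dmax is the maximum Euclidean
#' distance between states along the two lineages since their most recent
#' common ancestor (BM-reconstructed ancestors plus, by default, the tips
#' themselves, one state taken from each lineage). C1 near 1 means the tips
#' ended up far closer than their lineages ever were (convergence); C1 can
#' be negative when lineages diverge beyond any ancestral separation, and
#' negative values are reported, not clamped.
#'
#' @param tree an `ape::phylo`
#' @param scores `"morphospace"` or taxa x axes matrix (all axes used)
#' @param tip_a,tip_b tip labels (distinct)
#' @param ancestors_only if `TRUE`, exclude the tips from the Dmax candidate
#'   set (the stricter literal "between ancestral nodes" reading)
#' @return list `C1`, `Dtip`, `Dmax`
#' @export
c1_pair <- function(tree, scores, tip_a, tip_b, ancestors_only = FALSE) {
  if (identical(tip_a, tip_b)) stop("tip_a and tip_b must differ")
  Y <- .tip_matrix(tree, .score_matrix(scores))
  ancY <- ancestral_states_bm(tree, Y)
  info <- .c1_pairs_info(tree, c(tip_a, tip_b))[[1L]]
  v <- .c1_eval(Y, ancY, info, include_tips = !ancestors_only)
  if (v[["Dmax"]] == 0) {
    warning("Dmax = 0 (no phenotypic variation along lineages); C1 set to 0")
  }
  as.list(v)
}

#' Group convergence test: mean C1 against a Brownian-motion null
#'
#' The observed statistic is the mean pairwise C1 over all pairs of focal
#' taxa (e.g. the suction specialists). The null distribution is obtained by
#' re-simulating tip values under multivariate Brownian motion on the same
#' tree, with the rate matrix estimated from the observed scores
#' ([estimate_rate_matrix()]) and the root at the GLS ancestral mean, and
#' recomputing the statistic for each replicate;
#' \eqn{p = (1 + \#\{sim \ge obs\}) / (n_{sim} + 1)}. A high p means the
#' focal taxa are no closer in morphospace than drift alone predicts.
#'
#' @inheritParams c1_pair
#' @param focal character vector of at least two focal tip labels
#' @param n_sim number of BM simulations (default 1000)
#' @param seed optional integer seed
#' @param diagonal_rate if `TRUE`, use only the per-axis rates (diagonal of
#'   the estimated rate matrix) in the null simulations
#' @return list of class `"convergence_result"`: `pairs` (data frame tip_a,
#'   tip_b, C1, Dtip, Dmax), `mean_c1`, `p_value`, `n_sim`, `seed`
#' @export
c1_group_test <- function(tree, scores, focal, n_sim = 1000L, seed = NULL,
                          ancestors_only = FALSE, diagonal_rate = FALSE) {
  if (length(focal) < 2L) stop("need at least 2 focal taxa")
  if (n_sim < 100L) warning("n_sim < 100 gives coarse p-value resolution")
  Y <- .tip_matrix(tree, .score_matrix(scores))
  focal_tips <- tree$tip.label[match(normalize_taxon(focal),
                                     normalize_taxon(tree$tip.label))]
  if (anyNA(focal_tips)) {
    stop("focal taxa absent from tree: ",
         paste(focal[is.na(focal_tips)], collapse = ", "))
  }
  A <- .anc_operator(tree)
  ancY <- A %*% Y
  info <- .c1_pairs_info(tree, focal_tips)
  include_tips <- !ancestors_only
  obs <- t(vapply(info, .c1_eval, numeric(3), tipY = Y, ancY = ancY,
                  include_tips = include_tips))
  mean_obs <- mean(obs[, "C1"])
  rate <- estimate_rate_matrix(tree, Y)
  if (diagonal_rate) rate <- diag(diag(rate), nrow = nrow(rate))
  root <- phylo_mean(tree, Y)
  V <- phylo_vcv(tree)
  n <- nrow(V)
  k <- ncol(Y)
  eps <- 1e-8 * max(diag(V))
  Lv <- t(tryCatch(chol(V), error = function(e) chol(V + eps * diag(n))))
  Mr <- .psd_sqrt(rate)
  if (!is.null(seed)) set.seed(seed)
  hits <- 0L
  for (s in seq_len(n_sim)) {
    Z <- matrix(stats::rnorm(n * k), n, k)
    Ys <- sweep(Lv %*% Z %*% Mr, 2L, root, `+`)
    rownames(Ys) <- tree$tip.label
    ancS <- A %*% Ys
    m <- mean(vapply(info, function(pr) {
      .c1_eval(Ys, ancS, pr, include_tips = include_tips)[["C1"]]
    }, numeric(1)))
    if (m >= mean_obs) hits <- hits + 1L
  }
  structure(
    list(
      pairs = data.frame(
        tip_a = vapply(info, `[[`, "", "tip_a"),
        tip_b = vapply(info, `[[`, "", "tip_b"),
        C1 = obs[, "C1"], Dtip = obs[, "Dtip"], Dmax = obs[, "Dmax"],
        row.names = NULL, stringsAsFactors = FALSE
      ),
      mean_c1 = mean_obs, p_value = (1 + hits) / (n_sim + 1),
      n_sim = as.integer(n_sim), seed = seed
    ),
    class = "convergence_result"
  )
}

#' @export
print.convergence_result <- function(x, ...) {
  cat(sprintf("mean C1 = %.4f over %d focal pairs; p = %.4g (%d BM simulations)\n",
              x$mean_c1, nrow(x$pairs), x$p_value, x$n_sim))
  invisible(x)
}
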