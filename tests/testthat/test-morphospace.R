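test_that("standardized PCA matches an eigen-decomposition oracle", {
  set.seed(4)
  for (r in 1:5) {
    S <- matrix(rnorm(20), 5, 4,
                dimnames = list(paste0("t", 1:5), paste0("c", 1:4)))
    ms <- standardized_pca(S)
    Z <- scale(S, center = TRUE, scale = TRUE)
    ev <- eigen(cov(Z), symmetric = TRUE)
    expect_equal(ms$sdev^2, ev$values[seq_along(ms$sdev)], tolerance = 1e-8)
    expect_equal(ms$var_fraction, ev$values / sum(ev$values),
                 tolerance = 1e-8)
    for (j in 1:2) {  # scores match up to the fixed sign convention
      expect_equal(abs(ms$scores[, j]), abs(drop(Z %*% ev$vectors[, j])),
                   tolerance = 1e-8, ignore_attr = TRUE)
    }
    # reconstruction of the standardized matrix from scores and loadings
    expect_equal(ms$scores %*% t(ms$loadings), Z, tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(sum(ms$var_fraction), 1, tolerance = 1e-12)
    expect_lt(max(abs(colMeans(ms$scores))), 1e-10)
  }
})

test_that("two perfectly correlated characters load on a single axis", {
  S <- cbind(c1 = c(0, 1, 2, 3), c2 = c(0, 2, 4, 6) / 2)
  rownames(S) <- paste0("t", 1:4)
  ms <- standardized_pca(S)
  expect_equal(ms$var_fraction[1], 1, tolerance = 1e-12)
})

test_that("degenerate characters are dropped or refused with context", {
  S <- cbind(a = c(1, 1, 1), b = c(0, 1, 2), c = c(2, 0, 1))
  rownames(S) <- paste0("t", 1:3)
  expect_warning(ms <- standardized_pca(S), "zero-variance.*a")
  expect_equal(ms$dropped, "a")
  expect_error(suppressWarnings(standardized_pca(cbind(a = c(1, 1),
                                                       b = c(2, 2)))),
               "nonzero variance")
  S[2, 2] <- NA
  expect_error(standardized_pca(S), "impute_mean")
  expect_warning(standardized_pca(S, impute_mean = TRUE), "zero-variance")
})

test_that("axis signs are deterministic across equivalent inputs", {
  set.seed(10)
  S <- matrix(rnorm(48), 12, 4,
              dimnames = list(paste0("t", 1:12), paste0("c", 1:4)))
  ms1 <- standardized_pca(S)
  ms2 <- standardized_pca(S[sample(12), ])
  expect_equal(ms1$loadings, ms2$loadings, tolerance = 1e-10)
  for (j in seq_len(ncol(ms1$loadings))) {
    expect_gt(ms1$loadings[which.max(abs(ms1$loadings[, j])), j], 0)
  }
})

test_that("phylomorphospace nodes are the BM ancestral estimates", {
  tr <- balanced4()
  Y <- cbind(PC1 = c(A = 0, B = 6, C = 5, D = 7),
             PC2 = c(A = 1, B = 1, C = 1, D = 1))
  pm <- phylomorphospace(tr, Y)
  expect_equal(pm$node_coords,
               ancestral_states_bm(tr, Y), tolerance = 1e-12)
  expect_equal(nrow(pm$edges), nrow(tr$edge))
  # all tips at one point puts every ancestor at that point
  Y1 <- cbind(PC1 = rep(2, 4), PC2 = rep(-1, 4))
  rownames(Y1) <- tr$tip.label
  pm1 <- phylomorphospace(tr, Y1)
  expect_true(all(abs(sweep(pm1$node_coords, 2, c(2, -1))) < 1e-10))
  # two-tip tree with equal branches: root at the midpoint
  pm2 <- phylomorphospace(parse_newick("(A:1,B:1);"),
                          cbind(PC1 = c(A = 0, B = 4), PC2 = c(A = 2, B = 0)))
  expect_equal(unname(pm2$node_coords[1, ]), c(2, 1))
})

test_that("C1 takes its hand-computed value on a 4-tip tree", {
  tr <- balanced4()
  y <- cbind(trait = c(A = 0, B = 6, C = 5, D = 7))
  # squared-change/ML reconstruction: M = 3.5, N = 5.5, root = 4.5
  anc <- ancestral_states_bm(tr, y)
  expect_equal(unname(drop(anc)), c(4.5, 3.5, 5.5), tolerance = 1e-10)
  expect_equal(drop(anc), brute_force_anc(tr, drop(y)), tolerance = 1e-6)
  # pair (B, C): Dtip = 1; lineage states {4.5, 3.5, 6} x {4.5, 5.5, 5}
  # -> Dmax = |3.5 - 5.5| = 2; C1 = 1 - 1/2
  r <- c1_pair(tr, y, "B", "C")
  expect_equal(r$Dtip, 1)
  expect_equal(r$Dmax, 2, tolerance = 1e-10)
  expect_equal(r$C1, 0.5, tolerance = 1e-10)
  # excluding the tips shrinks the candidate set: Dmax = |3.5 - 5.5| = 2
  r2 <- c1_pair(tr, y, "B", "C", ancestors_only = TRUE)
  expect_equal(r2$Dmax, 2, tolerance = 1e-10)
  expect_error(c1_pair(tr, y, "B", "B"), "must differ")
})

test_that("C1 hits its boundary cases", {
  tr <- balanced4()
  # identical tip phenotypes in different clades: maximal convergence
  y <- cbind(t1 = c(A = 1, B = 0, C = 1, D = 3))
  r <- c1_pair(tr, y, "A", "C")
  expect_equal(r$Dtip, 0)
  expect_equal(r$C1, 1)
  # tips that are the most-different states on their lineages: C1 = 0
  y2 <- cbind(t1 = c(A = -4, B = 0, C = 4, D = 0))
  r2 <- c1_pair(tr, y2, "A", "C")
  expect_equal(r2$C1, 0, tolerance = 1e-10)
  # no variation at all: Dmax = 0 reported as C1 = 0 with a warning
  y3 <- cbind(t1 = c(A = 1, B = 1, C = 1, D = 1))
  expect_warning(r3 <- c1_pair(tr, y3, "A", "C"), "Dmax = 0")
  expect_equal(r3$C1, 0)
})

test_that("C1 is invariant to rigid rotation of the coordinates", {
  set.seed(17)
  tr <- simulate_yule_tree(16, 1)
  Y <- do.call(cbind, lapply(1:3, function(i) {
    drop(simulate_bm(tr, matrix(1))[[1]])
  }))
  colnames(Y) <- paste0("PC", 1:3)
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  a <- c1_pair(tr, Y, "t1", "t5")
  b <- c1_pair(tr, Y %*% Q, "t1", "t5")
  expect_equal(b$C1, a$C1, tolerance = 1e-10)
  expect_equal(b$Dtip, a$Dtip, tolerance = 1e-10)
})

test_that("the group test detects planted convergence and reproduces by seed", {
  set.seed(23)
  tr <- simulate_yule_tree(32, 1)
  Y <- do.call(cbind, lapply(1:3, function(i) {
    drop(simulate_bm(tr, matrix(1))[[1]])
  }))
  colnames(Y) <- paste0("PC", 1:3)
  focal <- c("t3", "t9", "t20", "t28")
  Y[focal, ] <- matrix(rep(c(5, -5, 2), each = 4), 4, 3)  # forced identical
  res <- c1_group_test(tr, Y, focal, n_sim = 199, seed = 5)
  expect_equal(res$mean_c1, 1)
  expect_lte(res$p_value, 2 / 200 + 0.02)
  res2 <- c1_group_test(tr, Y, focal, n_sim = 199, seed = 5)
  expect_identical(res2$p_value, res$p_value)
  expect_warning(c1_group_test(tr, Y, focal, n_sim = 50, seed = 1), "coarse")
  expect_error(c1_group_test(tr, Y, "t1", n_sim = 199), "at least 2 focal")
})
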