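# Shared fixtures and independent oracles. All fixtures are built in code.

tree3 <- function() parse_newick("((A:1,B:1):1,C:2);")

star4 <- function(depth = 2) {
  parse_newick(sprintf("(A:%g,B:%g,C:%g,D:%g);", depth, depth, depth, depth))
}

balanced4 <- function() parse_newick("((A:1,B:1):1,(C:1,D:1):1);")

# random valid ordinal character matrix (taxa x characters)
random_matrix <- function(n_taxa = 6, n_char = 5, binary_col = NULL,
                          missing_frac = 0) {
  s <- matrix(sample(0:3, n_taxa * n_char, replace = TRUE), n_taxa, n_char,
              dimnames = list(paste0("t", seq_len(n_taxa)),
                              paste0("c", seq_len(n_char))))
  if (!is.null(binary_col)) {
    s[, binary_col] <- sample(c(0, 3), n_taxa, replace = TRUE)
  }
  if (missing_frac > 0) {
    idx <- sample(length(s), ceiling(missing_frac * length(s)))
    s[idx] <- NA
  }
  s
}

# Independent oracle: joint BM ancestral states by numeric minimization of
# the weighted squared-change objective sum((x_child - x_parent)^2 / length).
brute_force_anc <- function(tree, tip_values) {
  n <- ape::Ntip(tree)
  m <- tree$Nnode
  y <- tip_values[tree$tip.label]
  obj <- function(theta) {
    st <- c(y, theta)
    sum((st[tree$edge[, 2]] - st[tree$edge[, 1]])^2 / tree$edge.length)
  }
  fit <- optim(rep(mean(y), m), obj, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 2000))
  setNames(fit$par, as.character(n + seq_len(m)))
}

# Independent oracle: exact one-sided binomial tail by enumeration.
enum_binom_tail <- function(correct, n, p) {
  j <- correct:n
  sum(choose(n, j) * p^j * (1 - p)^(n - j))
}

# Independent oracle: least squares by explicit normal equations.
brute_force_ls <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)
}
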