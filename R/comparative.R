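#' Kruskal-Wallis rank-sum comparison of score distributions
#'
#' Wrapper around [stats::kruskal.test()] that also reports the tie
#' correction applied, \eqn{1 - \sum(t^3 - t) / (N^3 - N)}. With two groups
#' (Suction vs Other) this is the rank-sum comparison used per character and
#' for the composite indices.
#'
#' @param values numeric vector of scores
#' @param groups group labels (factor or character), at least two non-empty
#'   groups
#' @return list of class `"group_comparison"`: `H`, `df`, `p`,
#'   `tie_correction`
#' @examples
#' kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))  # H = 27/7
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L || any(table(groups) == 0L)) {
    stop("at least two non-empty groups required")
  }
  N <- length(values)
  tt <- table(values)
  tie_c <- 1 - sum(tt^3 - tt) / (N^3 - N)
  if (length(unique(values)) == 1L) {
    warning("all values identical; H = 0 by convention (tie correction degenerate)")
    out <- list(H = 0, df = nlevels(groups) - 1L, p = 1, tie_correction = 0)
  } else {
    kt <- stats::kruskal.test(values, groups)
    out <- list(
      H = unname(kt$statistic),
      df = unname(kt$parameter),
      p = kt$p.value,
      tie_correction = tie_c
    )
  }
  structure(out, class = "group_comparison")
}

#' Blomberg's K phylogenetic signal with permutation test
#'
#' \eqn{K = (MSE_0 / MSE)_{obs} / (MSE_0 / MSE)_{exp}} where
#' \eqn{MSE_0 = (y - \hat a)'(y - \hat a) / (n - 1)} uses the GLS
#' phylogenetic mean \eqn{\hat a},
#' \eqn{MSE = (y - \hat a)' V^{-1} (y - \hat a) / (n - 1)}, and the
#' Brownian-motion expectation of the ratio is
#' \eqn{[tr(V) - n / (1' V^{-1} 1)] / (n - 1)}. K = 1 is the BM expectation;
#' larger K means more signal than BM predicts. Significance is assessed by
#' shuffling values across tips: signal makes the observed MSE small, so
#' \eqn{p = (1 + \#\{MSE_{perm} \le MSE_{obs}\}) / (n_{perm} + 1)}.
#'
#' @param tree an `ape::phylo`
#' @param values named numeric vector of tip values
#' @param n_perm number of tip-label permutations (default 1000)
#' @param seed optional integer seed
#' @return list of class `"phylo_signal"`: `K`, `p_perm`, `n_perm`, `seed`
#' @export
blomberg_k <- function(tree, values, n_perm = 1000L, seed = NULL) {
  y <- drop(.tip_matrix(tree, values))
  n <- length(y)
  if (n < 4L) stop("Blomberg's K needs at least 4 tips")
  V <- phylo_vcv(tree)
  iV <- .inv_vcv(V)
  expected <- (sum(diag(V)) - n / sum(iV)) / (n - 1)
  mse_ratio <- function(yy) {
    a <- sum(iV %*% yy) / sum(iV)
    d <- yy - a
    c(num = sum(d * d), den = drop(crossprod(d, iV %*% d)))
  }
  obs <- mse_ratio(y)
  K <- (obs["num"] / obs["den"]) / expected
  if (!is.null(seed)) set.seed(seed)
  hits <- 0L
  for (r in seq_len(n_perm)) {
    pm <- mse_ratio(sample(y))
    if (pm["den"] <= obs["den"]) hits <- hits + 1L
  }
  structure(
    list(K = unname(K), p_perm = (1 + hits) / (n_perm + 1),
         n_perm = as.integer(n_perm), seed = seed),
    class = "phylo_signal"
  )
}

#' Phylogenetic generalized least squares (and OLS) regression
#'
#' Closed-form GLS fit of `response ~ predictor` with residual covariance
#' proportional to the Brownian-motion tree covariance V:
#' \eqn{\hat\beta = (X' V^{-1} X)^{-1} X' V^{-1} y}, standard errors from
#' \eqn{\hat\sigma^2 (X' V^{-1} X)^{-1}} with
#' \eqn{\hat\sigma^2 = RSS_{GLS} / (n - p)}, and two-sided t tests on
#' n - p degrees of freedom. With `tree = NULL`, V is the identity and the
#' fit is ordinary least squares.
#'
#' A two-level feeding-mode predictor is coded Other = 0, Suction = 1, so a
#' positive coefficient means higher scores in suction feeders.
#'
#' @param response named numeric vector (e.g. a character score or SSI)
#' @param predictor named numeric vector, or a two-level label vector
#'   (values `Suction`/`Other`)
#' @param tree an `ape::phylo`, or `NULL` for OLS
#' @return list of class `"pgls_fit"`: `model` (`"PGLS_BM"` or `"OLS"`),
#'   `coefficients` (data frame: estimate, se, t, p), `sigma2`, `df_residual`,
#'   `logLik`
#' @export
pgls_fit <- function(response, predictor, tree = NULL) {
  nm <- names(response)
  if (is.null(nm)) stop("response must be named by taxon")
  if (is.character(predictor) || is.factor(predictor)) {
    pv <- as.character(predictor)
    if (!all(pv %in% c("Suction", "Other"))) {
      stop("two-level predictor must use labels Suction/Other")
    }
    predictor <- stats::setNames(as.numeric(pv == "Suction"), names(predictor))
  }
  px <- predictor[match(normalize_taxon(nm), normalize_taxon(names(predictor)))]
  if (anyNA(px)) stop("predictor missing for some taxa")
  if (!is.null(tree)) {
    Y <- .tip_matrix(tree, cbind(y = response))
    x <- px[match(normalize_taxon(rownames(Y)), normalize_taxon(nm))]
    y <- drop(Y)
    V <- phylo_vcv(tree)
    model <- "PGLS_BM"
  } else {
    y <- as.numeric(response)
    x <- as.numeric(px)
    V <- diag(length(y))
    model <- "OLS"
  }
  n <- length(y)
  X <- cbind(`(Intercept)` = 1, predictor = x)
  p <- ncol(X)
  if (qr(X)$rank < p) stop("rank-deficient design matrix")
  eps <- 1e-8 * max(diag(V))
  ch <- tryCatch(chol(V), error = function(e) chol(V + eps * diag(n)))
  # whiten: solve(t(ch)) %*% . ; then ordinary LS
  Xw <- backsolve(ch, X, transpose = TRUE)
  yw <- backsolve(ch, y, transpose = TRUE)
  XtX <- crossprod(Xw)
  XtXi <- solve(XtX)
  beta <- drop(XtXi %*% crossprod(Xw, yw))
  resid_w <- yw - Xw %*% beta
  rss <- sum(resid_w^2)
  sigma2 <- rss / (n - p)
  se <- sqrt(diag(XtXi) * sigma2)
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), df = n - p, lower.tail = FALSE)
  s2_ml <- rss / n
  ldetV <- 2 * sum(log(diag(ch)))
  ll <- -0.5 * (n * log(2 * pi * s2_ml) + ldetV + n)
  structure(
    list(
      model = model,
      coefficients = data.frame(
        term = colnames(X), estimate = beta, se = se, t = tval, p = pval,
        row.names = NULL, stringsAsFactors = FALSE
      ),
      sigma2 = sigma2, df_residual = n - p, logLik = ll
    ),
    class = "pgls_fit"
  )
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("%s fit (df resid %d, sigma2 %.4g)\n", x$model,
              x$df_residual, x$sigma2))
  print(x$coefficients, digits = 4)
  invisible(x)
}
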