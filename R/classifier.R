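#' Stratified train/test partition of labelled taxa
#'
#' Splits the labelled taxa into training and testing sets, sampling within
#' each feeding-mode class so that class proportions are preserved. The
#' per-class test count is `test_fraction * class size` rounded under
#' `rounding`; the default round-half-down gives, for classes of 42 and 26
#' at fraction 0.25, test counts 10 and 6 (n_test = 16, majority share
#' 0.625).
#'
#' @param labels named vector of `"Suction"`/`"Other"` (see [label_table()])
#' @param test_fraction proportion of each class held out (default 0.25)
#' @param seed integer seed
#' @param rounding `"half_down"` (default) or `"half_up"`
#' @return list of class `"partition"`: `train`, `test` (taxon name
#'   vectors), `seed`, `counts` (per-class train/test table)
#' @export
stratified_partition <- function(labels, test_fraction = 0.25, seed = 1L,
                                 rounding = c("half_down", "half_up")) {
  rounding <- match.arg(rounding)
  stopifnot(test_fraction > 0, test_fraction < 1)
  cls <- split(names(labels), unname(labels))
  if (length(cls) < 2L || any(lengths(cls) < 2L)) {
    stop("both classes need at least 2 members")
  }
  rnd <- function(x) {
    if (rounding == "half_down") ceiling(x - 0.5) else floor(x + 0.5)
  }
  set.seed(seed)
  test <- character(0)
  counts <- list()
  for (cl in names(cls)) {
    n_cl <- length(cls[[cl]])
    n_t <- rnd(n_cl * test_fraction)
    if (n_t < 1L) {
      stop(sprintf("class '%s' (n = %d) gets no test member at fraction %g",
                   cl, n_cl, test_fraction))
    }
    if (n_t >= n_cl) stop(sprintf("class '%s' fully consumed by test set", cl))
    test <- c(test, sample(cls[[cl]], n_t))
    counts[[cl]] <- c(train = n_cl - n_t, test = n_t)
  }
  structure(
    list(train = setdiff(names(labels), test), test = test,
         seed = as.integer(seed), counts = counts),
    class = "partition"
  )
}

# Ridge-stabilised logistic regression by IRLS. The ridge (default 1e-8)
# keeps the solve well-posed under complete separation, where unpenalised ML
# weights diverge; at this magnitude predictions on finite data are
# unaffected and the fit matches unregularised glm to ~1e-4 when classes
# overlap.
.fit_logit <- function(X, y01, ridge = 1e-8, max_iter = 200L, tol = 1e-10) {
  p <- ncol(X)
  beta <- rep(0, p)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y01 - mu) / w
    XtWX <- crossprod(X, w * X) + ridge * diag(p)
    beta_new <- drop(solve(XtWX, crossprod(X, w * z)))
    if (max(abs(beta_new - beta)) < tol * (1 + max(abs(beta)))) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
  }
  list(coef = stats::setNames(beta, colnames(X)), converged = converged)
}

#' Fit a logistic (two-class multinomial) suction classifier
#'
#' Maximum-likelihood logistic regression of feeding mode (Suction = 1,
#' Other = 0) on one or more character scores, fitted by iteratively
#' reweighted least squares with a tiny ridge term so that perfectly
#' separating predictors (the best characters in practice) still converge.
#'
#' @param x a [character_matrix()] or a numeric matrix with taxon rownames
#'   (columns may include composite indices)
#' @param labels named `"Suction"`/`"Other"` vector
#' @param predictors character vector of column names to use
#' @param train character vector of training taxon names
#' @param ridge ridge penalty on the weights (default 1e-8)
#' @return object of class `"suction_classifier"`: `predictors`, `coef`
#'   (intercept + one weight per predictor), `converged`, `ridge`
#' @export
fit_logistic <- function(x, labels, predictors, train, ridge = 1e-8) {
  S <- if (inherits(x, "character_matrix")) x$scores else x
  missing_p <- setdiff(predictors, colnames(S))
  if (length(missing_p) > 0L) {
    stop("unknown predictor(s): ", paste(missing_p, collapse = ", "))
  }
  if (length(train) < 1L) stop("empty training set")
  idx <- match(normalize_taxon(train), normalize_taxon(rownames(S)))
  if (anyNA(idx)) stop("training taxa absent from matrix")
  y <- labels[match(normalize_taxon(train), normalize_taxon(names(labels)))]
  if (anyNA(y)) stop("training taxa absent from labels")
  if (length(unique(y)) < 2L) stop("training set contains a single class")
  X <- cbind(`(Intercept)` = 1, S[idx, predictors, drop = FALSE])
  fit <- .fit_logit(X, as.numeric(y == "Suction"), ridge = ridge)
  structure(
    list(predictors = predictors, coef = fit$coef,
         converged = fit$converged, ridge = ridge),
    class = "suction_classifier"
  )
}

#' @export
#' @rdname fit_logistic
#' @param object a fitted `suction_classifier`
#' @param newdata matrix or `character_matrix` with the predictor columns
#' @param taxa_names which taxa to predict (default all rows)
#' @param ... unused
predict.suction_classifier <- function(object, newdata, taxa_names = NULL,
                                       ...) {
  S <- if (inherits(newdata, "character_matrix")) newdata$scores else newdata
  if (is.null(taxa_names)) taxa_names <- rownames(S)
  idx <- match(normalize_taxon(taxa_names), normalize_taxon(rownames(S)))
  if (anyNA(idx)) stop("taxa absent from matrix")
  X <- cbind(1, S[idx, object$predictors, drop = FALSE])
  score <- drop(X %*% object$coef)
  stats::setNames(ifelse(score > 0, "Suction", "Other"), taxa_names)
}

#' Exact binomial machinery for accuracy vs the no-information rate
#'
#' Clopper-Pearson two-sided 95\% confidence interval for the test-set
#' accuracy `correct / n_test` (via [stats::binom.test()]) and the one-sided
#' exact binomial tail \eqn{P(X \ge correct \mid n, NIR)} against the
#' no-information rate (majority-class share).
#'
#' @param correct number of correct test predictions
#' @param n_test test-set size
#' @param nir no-information rate in (0, 1)
#' @return list `ci_low`, `ci_high`, `p_vs_nir`
#' @examples
#' nir_test(16, 16, 0.625)  # ci (0.7941, 1), p = 0.625^16
#' @export
nir_test <- function(correct, n_test, nir) {
  stopifnot(correct >= 0, correct <= n_test, nir > 0, nir < 1)
  ci <- stats::binom.test(correct, n_test)$conf.int
  p <- stats::pbinom(correct - 1, n_test, nir, lower.tail = FALSE)
  list(ci_low = ci[1L], ci_high = ci[2L], p_vs_nir = p)
}

#' Evaluate a classifier on a test set
#'
#' Confusion matrix (rows = truth, cols = prediction, Suction first),
#' accuracy, precision, recall and F1 with Suction as the positive class,
#' the no-information rate of the test set, and exact binomial inference for
#' accuracy vs NIR ([nir_test()]). A zero-denominator precision/recall/F1 is
#' reported as `NA` (undefined), never as 0.
#'
#' @param model a `suction_classifier`
#' @param x matrix or `character_matrix`
#' @param labels named label vector
#' @param test character vector of test taxon names
#' @return list of class `"classification_report"`
#' @export
evaluate <- function(model, x, labels, test) {
  if (length(test) < 1L) stop("empty test set")
  pred <- predict(model, x, taxa_names = test)
  truth <- labels[match(normalize_taxon(test), normalize_taxon(names(labels)))]
  if (anyNA(truth)) stop("test taxa absent from labels")
  lv <- c("Suction", "Other")
  cm <- table(factor(truth, lv), factor(pred, lv))
  confusion <- matrix(as.integer(cm), 2, 2, dimnames = dimnames(cm))
  n_test <- length(test)
  tp <- confusion[1L, 1L]; fn <- confusion[1L, 2L]
  fp <- confusion[2L, 1L]; tn <- confusion[2L, 2L]
  accuracy <- (tp + tn) / n_test
  precision <- if (tp + fp > 0L) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  nir <- max(table(truth)) / n_test
  nt <- nir_test(round(accuracy * n_test), n_test, nir)
  structure(
    list(confusion = confusion, accuracy = accuracy, precision = precision,
         recall = recall, f1 = f1, n_test = n_test, nir = nir,
         ci_low = nt$ci_low, ci_high = nt$ci_high, p_vs_nir = nt$p_vs_nir),
    class = "classification_report"
  )
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f (95%% CI %.4f-%.4f), NIR %.4f, p vs NIR %.4g\n",
              x$accuracy, x$ci_low, x$ci_high, x$nir, x$p_vs_nir))
  print(x$confusion)
  invisible(x)
}

#' Run the full predictor battery
#'
#' Fits and evaluates, on one shared stratified partition, the table of
#' models used to rank predictors of suction feeding: a single-variable
#' logistic model per character, single-variable models for the composite
#' indices CharSum, CharMean (the SSI) and the adjusted SSI, a multivariate
#' model over all characters, and a multivariate model over the
#' osteological/dentition characters only.
#'
#' @param x a [character_matrix()]
#' @param labels named `"Suction"`/`"Other"` vector covering the taxa of `x`
#' @param ssi_table optional precomputed [compute_ssi()] table
#' @param test_fraction held-out fraction per class (default 0.25)
#' @param seed integer seed for the partition
#' @param resplit_per_model if `TRUE`, draw a fresh partition (seeds
#'   `seed + model index`) for every model instead of sharing one split
#' @return list of class `"battery_report"`: `table` (data frame with one
#'   row per model: predictor, accuracy, ci_low, ci_high, p_vs_nir,
#'   precision, recall, f1), `reports` (full `classification_report`s),
#'   `partition`, `nir`, `seed`
#' @export
run_predictor_battery <- function(x, labels, ssi_table = NULL,
                                  test_fraction = 0.25, seed = 1L,
                                  resplit_per_model = FALSE) {
  stopifnot(inherits(x, "character_matrix"))
  labels <- labels[match(normalize_taxon(taxa(x)),
                         normalize_taxon(names(labels)))]
  names(labels) <- taxa(x)
  if (anyNA(labels)) stop("labels missing for some taxa in the matrix")
  if (is.null(ssi_table)) ssi_table <- compute_ssi(x)
  aug <- cbind(
    x$scores,
    CharSum = ssi_table$char_sum[match(taxa(x), ssi_table$taxon)],
    CharMean = ssi_table$char_mean[match(taxa(x), ssi_table$taxon)],
    AdjustedSSI = ssi_table$adjusted_ssi[match(taxa(x), ssi_table$taxon)]
  )
  osteo <- characters(x)[x$char_class == "osteo_dental"]
  specs <- c(
    lapply(characters(x), function(ch) list(name = ch, pred = ch)),
    list(
      list(name = "CharSum", pred = "CharSum"),
      list(name = "CharMean", pred = "CharMean"),
      list(name = "AdjustedSSI", pred = "AdjustedSSI"),
      list(name = "multivariate_all", pred = characters(x)),
      list(name = "multivariate_osteo_dental", pred = osteo)
    )
  )
  part <- stratified_partition(labels, test_fraction, seed)
  reports <- vector("list", length(specs))
  names(reports) <- vapply(specs, `[[`, "", "name")
  for (i in seq_along(specs)) {
    pi <- if (resplit_per_model) {
      stratified_partition(labels, test_fraction, seed + i)
    } else part
    mod <- fit_logistic(aug, labels, specs[[i]]$pred, pi$train)
    reports[[i]] <- evaluate(mod, aug, labels, pi$test)
  }
  tab <- data.frame(
    predictor = names(reports),
    accuracy = vapply(reports, `[[`, 0, "accuracy"),
    ci_low = vapply(reports, `[[`, 0, "ci_low"),
    ci_high = vapply(reports, `[[`, 0, "ci_high"),
    p_vs_nir = vapply(reports, `[[`, 0, "p_vs_nir"),
    precision = vapply(reports, `[[`, 0, "precision"),
    recall = vapply(reports, `[[`, 0, "recall"),
    f1 = vapply(reports, `[[`, 0, "f1"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(
    list(table = tab, reports = reports, partition = part,
         nir = reports[[1L]]$nir, seed = as.integer(seed)),
    class = "battery_report"
  )
}

#' @export
print.battery_report <- function(x, ...) {
  cat(sprintf("predictor battery: %d models, n_test %d, NIR %.4f\n",
              nrow(x$table), x$reports[[1L]]$n_test, x$nir))
  print(x$table, digits = 4)
  invisible(x)
}
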