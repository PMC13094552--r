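make_labels <- function(n_suction, n_other) {
  setNames(c(rep("Suction", n_suction), rep("Other", n_other)),
           paste0("t", seq_len(n_suction + n_other)))
}

test_that("stratified partitions preserve class proportions and reproduce", {
  lab <- make_labels(26, 42)
  p1 <- stratified_partition(lab, 0.25, seed = 3)
  expect_length(p1$test, 16L)
  expect_setequal(c(p1$train, p1$test), names(lab))
  expect_length(intersect(p1$train, p1$test), 0L)
  # per-class test share within 1/n_test of the full-data share
  sh_test <- mean(lab[p1$test] == "Suction")
  expect_lt(abs(sh_test - 26 / 68), 1 / 16)
  expect_identical(stratified_partition(lab, 0.25, seed = 3)$test, p1$test)
  expect_false(identical(stratified_partition(lab, 0.25, seed = 4)$test,
                         p1$test))
  expect_error(stratified_partition(make_labels(1, 10), 0.25, 1),
               "at least 2 members")
  expect_error(stratified_partition(make_labels(10, 40), 0.01, 1),
               "no test member")
})

test_that("round-half-down vs half-up rounding is honoured per class", {
  lab <- make_labels(26, 42)
  pd <- stratified_partition(lab, 0.25, seed = 1, rounding = "half_down")
  expect_equal(unname(sort(vapply(pd$counts, `[[`, 0, "test"))), c(6, 10))
  pu <- stratified_partition(lab, 0.25, seed = 1, rounding = "half_up")
  expect_equal(unname(sort(vapply(pu$counts, `[[`, 0, "test"))), c(7, 11))
})

test_that("logistic fits handle separation, constancy, and match glm", {
  set.seed(7)
  n <- 20
  x <- matrix(c(rep(0:1, each = n / 2), runif(n)), n, 2,
              dimnames = list(paste0("t", 1:n), c("sep", "noise")))
  lab <- setNames(ifelse(x[, "sep"] == 1, "Suction", "Other"), rownames(x))
  m <- fit_logistic(x, lab, "sep", rownames(x))
  expect_true(m$converged)
  expect_equal(unname(predict(m, x)), unname(lab))

  cst <- matrix(1, n, 1, dimnames = list(rownames(x), "flat"))
  lab2 <- setNames(rep(c("Suction", "Other"), c(4, 16)), rownames(x))
  m2 <- fit_logistic(cst, lab2, "flat", rownames(x))
  expect_true(all(predict(m2, cst) == "Other"))  # majority class

  # overlapping classes: agrees with unregularized ML (glm) to 1e-4
  x3 <- matrix(c(0.1, 0.4, 0.35, 0.8, 0.23, 0.61, 0.9, 0.05, 0.55, 0.7),
               ncol = 1, dimnames = list(paste0("t", 1:10), "v"))
  y3 <- setNames(c("Other", "Other", "Suction", "Suction", "Other",
                   "Suction", "Suction", "Other", "Other", "Suction"),
                 rownames(x3))
  m3 <- fit_logistic(x3, y3, "v", rownames(x3))
  ref <- glm(I(y3 == "Suction") ~ x3[, 1], family = binomial())
  expect_equal(unname(m3$coef), unname(coef(ref)), tolerance = 1e-4)
  expect_error(fit_logistic(x3, setNames(rep("Other", 10), rownames(x3)),
                            "v", rownames(x3)), "single class")
})

test_that("evaluation metrics follow the hand formulas", {
  # single threshold predictor: Suction iff score > 0
  n <- 16
  x <- matrix(0, n, 1, dimnames = list(paste0("t", 1:n), "v"))
  model <- structure(list(predictors = "v",
                          coef = c(`(Intercept)` = -1, v = 2),
                          converged = TRUE, ridge = 0),
                     class = "suction_classifier")
  # perfect: 10 Suction at v=1, 6 Other at v=0
  x[1:10, ] <- 1
  lab <- setNames(rep(c("Suction", "Other"), c(10, 6)), rownames(x))
  r <- evaluate(model, x, lab, rownames(x))
  expect_equal(unname(r$confusion), matrix(c(10, 0, 0, 6), 2, 2))
  expect_equal(c(r$accuracy, r$precision, r$recall, r$f1), c(1, 1, 1, 1))

  # one false negative: accuracy 15/16, F1 = 2*(9/10)/(1 + 9/10)
  x[10, ] <- 0
  r2 <- evaluate(model, x, lab, rownames(x))
  expect_equal(r2$accuracy, 15 / 16)
  expect_equal(r2$recall, 9 / 10)
  expect_equal(r2$f1, 2 * (9 / 10) / (1 + 9 / 10))
  expect_equal(r2$nir, 10 / 16)

  # predict-all-majority scores exactly NIR, precision undefined (NA)
  x[, 1] <- 0
  lab3 <- setNames(rep(c("Suction", "Other"), c(6, 10)), rownames(x))
  r3 <- evaluate(model, x, lab3, rownames(x))
  expect_equal(r3$accuracy, r3$nir)
  expect_true(is.na(r3$precision))
  expect_true(is.na(r3$f1))
})

test_that("exact binomial machinery agrees with enumeration for n <= 30", {
  for (n in c(5, 16, 30)) {
    for (correct in c(0, 1, floor(n / 2), n - 1, n)) {
      nt <- nir_test(correct, n, 0.625)
      expect_equal(nt$p_vs_nir, enum_binom_tail(correct, n, 0.625),
                   tolerance = 1e-12)
      expect_lte(nt$ci_low, correct / n)
      expect_gte(nt$ci_high, correct / n)
    }
  }
  expect_equal(nir_test(0, 16, 0.625)$p_vs_nir, 1)
})

test_that("Clopper-Pearson intervals have at least nominal coverage", {
  set.seed(33)
  p_true <- 0.8
  draws <- rbinom(10000, 16, p_true)
  covered <- vapply(draws, function(k) {
    ci <- nir_test(k, 16, 0.5)
    ci$ci_low <= p_true && p_true <= ci$ci_high
  }, logical(1))
  expect_gte(mean(covered), 0.95)
})

test_that("the battery flags a perfectly separating character", {
  ds <- generate_dataset(synth_config(seed = 19))
  # force one character to separate the classes exactly
  ds$suction$scores[, "reduced_dentition"] <-
    ifelse(ds$labels[taxa(ds$suction)] == "Suction", 3, 0)
  bat <- run_predictor_battery(ds$suction, ds$labels, seed = 2)
  n_test <- bat$reports[[1]]$n_test
  strong <- bat$table[bat$table$predictor == "reduced_dentition", ]
  expect_equal(strong$accuracy, 1)
  expect_equal(strong$ci_low, 0.025^(1 / n_test), tolerance = 1e-6)
  # bit-reproducible given (matrix, labels, seed)
  bat2 <- run_predictor_battery(ds$suction, ds$labels, seed = 2)
  expect_identical(bat$table, bat2$table)
})

test_that("an all-zero matrix yields intercept-only models at NIR accuracy", {
  s <- matrix(0, 20, 3, dimnames = list(paste0("t", 1:20), c("a", "b", "c")))
  m <- character_matrix(s)
  lab <- make_labels(6, 14)
  bat <- run_predictor_battery(m, lab, seed = 5)
  expect_true(all(abs(bat$table$accuracy - bat$nir) < 1e-12))
})

test_that("with shuffled labels battery accuracies concentrate at NIR", {
  ds <- generate_dataset(synth_config(seed = 55, n_taxa = 40))
  set.seed(56)
  acc <- replicate(60, {
    lab <- setNames(sample(ds$labels), names(ds$labels))
    bat <- run_predictor_battery(ds$suction, lab, seed = sample.int(1e6, 1))
    mean(bat$table$accuracy) - bat$nir
  })
  expect_lt(abs(mean(acc)), 0.1)
})
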