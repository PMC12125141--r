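test_that("stratified folds balance both classes to within one member", {
  y <- rep(c(1, 0), c(14, 27))
  f <- stratified_folds(y, k = 5, seed = 1)
  pos <- table(f[y == 1]); neg <- table(f[y == 0])
  expect_true(all(pos %in% 2:3))
  expect_true(all(neg %in% 5:6))
  expect_identical(f, stratified_folds(y, k = 5, seed = 1))
  expect_false(identical(f, stratified_folds(y, k = 5, seed = 2)))
  expect_error(stratified_folds(rep(c(1, 0), c(3, 30)), k = 5), "at least")
})

test_that("a separating feature with a weak penalty fits the training data", {
  set.seed(1)
  X <- cbind(sep = c(rnorm(10, -3), rnorm(10, 3)), noise = rnorm(20))
  y <- rep(0:1, each = 10)
  fit <- fit_logistic(X, y, strength = 100)
  expect_equal(pshrisk:::roc_auc(y, predict(fit, X)), 1)
})

test_that("the penalty limit drives coefficients to zero and balanced predictions to 1/2", {
  set.seed(2)
  X <- matrix(rnorm(60), 20, 3)
  y <- rep(c(1, 0), c(6, 14))
  fit <- fit_logistic(X, y, strength = 1e-8, weighting = "balanced")
  expect_true(all(abs(fit$coef) < 1e-4))
  expect_true(all(abs(predict(fit, X) - 0.5) < 0.01))
  # unbalanced limit: the class prior
  fit2 <- fit_logistic(X, y, strength = 1e-8, weighting = "unbalanced")
  expect_true(all(abs(predict(fit2, X) - 0.3) < 0.01))
})

test_that("coefficients agree with an independent penalised-likelihood optimiser", {
  set.seed(3)
  X <- matrix(rnorm(30), 10, 3)
  y <- rep(c(0, 1), 5)
  for (C in c(0.5, 5)) {
    for (wgt in c("balanced", "unbalanced")) {
      fit <- fit_logistic(X, y, strength = C, weighting = wgt,
                          standardize = FALSE)
      w <- pshrisk:::class_weights(y, wgt)
      nll <- function(b) {
        eta <- b[1] + X %*% b[-1]
        sum(w * (log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta)) +
          sum(b[-1]^2) / (2 * C)
      }
      ref <- optim(rep(0, 4), nll, method = "BFGS",
                   control = list(maxit = 1000, reltol = 1e-14))
      expect_equal(unname(c(fit$intercept, fit$coef)), ref$par,
                   tolerance = 1e-6)
    }
  }
})

test_that("zero-variance columns are dropped with coefficient zero", {
  set.seed(4)
  X <- cbind(a = rnorm(20), flat = rep(2, 20))
  y <- rep(0:1, 10)
  expect_warning(fit <- fit_logistic(X, y, strength = 1), "zero-variance")
  expect_equal(unname(fit$coef["flat"]), 0)
  expect_equal(fit$dropped, "flat")
})

test_that("balanced and unbalanced weighting coincide for equal class sizes", {
  set.seed(5)
  X <- matrix(rnorm(40), 20, 2)
  y <- rep(0:1, each = 10)
  fb <- fit_logistic(X, y, strength = 2, weighting = "balanced")
  fu <- fit_logistic(X, y, strength = 2, weighting = "unbalanced")
  expect_equal(fb$coef, fu$coef, tolerance = 1e-8)
  expect_equal(fb$intercept, fu$intercept, tolerance = 1e-8)
})

test_that("AUC is invariant to strictly monotone score transforms", {
  set.seed(6)
  y <- rbinom(40, 1, 0.4)
  score <- rnorm(40)
  expect_equal(pshrisk:::roc_auc(y, score),
               pshrisk:::roc_auc(y, exp(3 * score)))
})

test_that("grid search explores the documented grid and prefers smaller strength on ties", {
  set.seed(7)
  n <- 30
  X <- cbind(sep = c(rnorm(10, -4), rnorm(20, 4)), n1 = rnorm(n))
  y <- rep(c(0, 1), c(10, 20))
  fm <- list(x = X, y = y, level = "I", metric = NULL, window_hours = NULL)
  cv <- grid_search_cv(fm, model_config(n, k_folds = 5, seed = 1))
  expect_equal(nrow(cv$grid), 10)
  expect_setequal(unique(cv$grid$strength),
                  c(2 * n, n, 1, 1 / n, 1 / (2 * n)))
  # perfect separation: every configuration reaches AUC 1; tie resolves
  # to the smallest strength
  expect_equal(cv$best$auc_mean, 1)
  expect_equal(cv$best$strength, 1 / (2 * n))
})

test_that("fold-local imputation and standardisation do not leak labels", {
  # canary: a feature equal to the label on one fold's validation rows
  # (and noise elsewhere) must not lift performance above the null band
  aucs <- sapply(1:5, function(s) {
    set.seed(s)
    n <- 100
    y <- rep(0:1, each = n / 2)[sample(n)]
    X <- matrix(rnorm(n * 5), n, 5,
                dimnames = list(NULL, paste0("x", 1:5)))
    folds <- stratified_folds(y, 5, seed = s)
    canary <- rnorm(n)
    canary[folds == 1] <- y[folds == 1]
    X[, 1] <- canary
    fm <- list(x = X, y = y, level = "I")
    grid_search_cv(fm, model_config(n, seed = s))$best$auc_mean
  })
  expect_lt(mean(aucs), 0.62)
})

test_that("missing features are imputed with training-fold medians", {
  set.seed(8)
  n <- 40
  X <- cbind(good = c(rnorm(20, -2), rnorm(20, 2)), holey = rnorm(n))
  X[sample(n, 10), "holey"] <- NA
  y <- rep(0:1, each = 20)
  fm <- list(x = X, y = y, level = "I")
  cv <- grid_search_cv(fm, model_config(n, seed = 1))
  expect_true(is.finite(cv$best$auc_mean))
  expect_gt(cv$best$auc_mean, 0.9)
})
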