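test_that("dataset split honors the fractions with leftover rows to validation", {
  sp <- split_dataset(100, seed = 5)
  expect_equal(lengths(sp[c("train", "validation", "test")]),
               c(train = 65L, validation = 25L, test = 10L))
  expect_equal(sort(c(sp$train, sp$validation, sp$test)), 1:100)
  sp10 <- split_dataset(10, seed = 5)
  expect_equal(lengths(sp10[c("train", "validation", "test")]),
               c(train = 6L, validation = 3L, test = 1L))
  expect_identical(split_dataset(57, seed = 9), split_dataset(57, seed = 9))
  expect_error(split_dataset(100, fractions = c(0.5, 0.3, 0.1)), "summing to 1")
  expect_error(split_dataset(5), "at least 10")
})

test_that("kernel values match closed forms and the squared-exponential limit", {
  rq <- kernel_spec("rational_quadratic", amplitude = 2, length_scale = 1.5)
  x <- c(1, 2, 3)
  expect_equal(kernel_value(rq, x, x), 2)
  # d = ell, alpha = 1, amplitude = 1 -> (1 + 1/2)^(-1) = 2/3
  rq1 <- kernel_spec("rational_quadratic", length_scale = 2, alpha = 1)
  expect_equal(kernel_value(rq1, c(0, 0), c(2, 0)), 2 / 3)
  # alpha -> Inf recovers the squared exponential
  se <- kernel_spec("squared_exponential", length_scale = 0.8)
  rq_big <- kernel_spec("rational_quadratic", length_scale = 0.8, alpha = 1e6)
  set.seed(3)
  for (i in 1:10) {
    a <- rnorm(4); b <- rnorm(4)
    expect_lt(abs(kernel_value(rq_big, a, b) - kernel_value(se, a, b)), 1e-6)
  }
  expect_error(kernel_value(rq, c(1, 2), c(1, 2, 3)), "dimension mismatch")
})

test_that("kernel matrices are symmetric positive semidefinite", {
  set.seed(41)
  for (family in c("rational_quadratic", "squared_exponential",
                   "matern52", "exponential")) {
    x <- matrix(rnorm(60), 20, 3)
    K <- kernel_matrix(kernel_spec(family, length_scale = 1.3), x)
    expect_equal(K, t(K), tolerance = 1e-12)
    expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
  }
})

test_that("models interpolate clean targets and absorb conflicting duplicates", {
  x <- data.frame(f = seq(0, 1, length.out = 20))
  y <- 0.02 + 0.05 * x$f                       # noise-free linear target
  lin <- fit_cream_model(x, y, spec = kernel_spec("linear"))
  expect_lt(max(abs(predict(lin, x) - y)), 1e-6)
  # noise-free GP with fixed tiny-noise kernel reproduces training targets
  gp <- fit_cream_model(x, y,
                        spec = kernel_spec("rational_quadratic",
                                           length_scale = 0.5, noise = 1e-10),
                        optimize = FALSE)
  expect_lt(max(abs(predict(gp, x) - y)), 1e-6)
  # duplicated features with conflicting targets: noise must absorb
  xd <- data.frame(f = rep(c(0.2, 0.8), each = 5))
  yd <- c(rep(0.04, 4), 0.08, rep(0.06, 4), 0.02)
  gp2 <- fit_cream_model(xd, yd, spec = kernel_spec("squared_exponential"),
                         restarts = 2, seed = 2)
  expect_gt(gp2$spec$noise, 1e-8)
  expect_true(all(is.finite(predict(gp2, xd))))
})

test_that("GP predictive uncertainty collapses at training points", {
  set.seed(12)
  x <- data.frame(f1 = runif(15), f2 = runif(15))
  y <- 0.05 + 0.02 * sin(4 * x$f1)
  m <- fit_cream_model(x, y,
                       spec = kernel_spec("squared_exponential",
                                          length_scale = 1, noise = 1e-8),
                       optimize = FALSE)
  at_train <- predict(m, x, se.fit = TRUE)
  far <- data.frame(f1 = 25, f2 = -30)
  at_far <- predict(m, far, se.fit = TRUE)
  expect_lt(max(at_train$se.fit), 1e-3)
  expect_gt(at_far$se.fit, 10 * max(at_train$se.fit))
  expect_true(all(at_train$se.fit >= 0))
  # constant features yield constant predictions
  const <- data.frame(f1 = rep(0.5, 4), f2 = rep(0.5, 4))
  expect_equal(diff(range(predict(m, const))), 0)
})

test_that("evaluation metrics match hand-computed cases", {
  truth <- c(0.05, 0.06, 0.07, 0.04)
  ev <- evaluate_predictions(truth, truth)
  expect_equal(ev$r2, 1)
  expect_equal(ev$mae, 0)
  expect_equal(ev$rmse, 0)
  expect_equal(ev$mean_bias, 0)
  ev_mean <- evaluate_predictions(rep(mean(truth), 4), truth)
  expect_equal(ev_mean$r2, 0)
  ev2 <- evaluate_predictions(c(0.05, 0.06), c(0.06, 0.05))
  expect_equal(ev2$mae, 0.01)
  expect_equal(ev2$rmse, 0.01)
  expect_equal(ev2$mean_bias, 0)
  expect_true(ev2$rmse >= ev2$mae)
  expect_error(evaluate_predictions(c(1, 2), c(3, 3)), "zero variance")
  expect_error(evaluate_predictions(1, 1), "equal length")
})

test_that("permutation importance singles out the informative feature", {
  set.seed(6)
  n <- 60
  x <- data.frame(f1 = runif(n), f2 = runif(n), f3 = runif(n))
  y <- 0.03 + 0.04 * x$f2
  m <- fit_cream_model(x[1:40, ], y[1:40],
                       spec = kernel_spec("squared_exponential"),
                       restarts = 2, seed = 3)
  imp <- permutation_importance(m, x[41:60, ], y[41:60], seed = 7)
  expect_equal(imp$feature[1], "f2")
  expect_gt(imp$importance[1], 5 * max(abs(imp$importance[-1])))
  imp2 <- permutation_importance(m, x[41:60, ], y[41:60], seed = 7)
  expect_identical(imp, imp2)
})

test_that("serialized models reload with bit-identical predictions", {
  set.seed(14)
  x <- data.frame(f1 = runif(12), f2 = runif(12))
  y <- runif(12, 0.04, 0.07)
  m <- fit_cream_model(x, y, spec = kernel_spec("rational_quadratic"),
                       restarts = 1, seed = 1)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(predict(m2, x), predict(m, x))
  # version mismatch is refused
  m_bad <- m; m_bad$version <- "milkcv-model-0"
  saveRDS(m_bad, path)
  expect_error(load_model(path), "version")
})
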