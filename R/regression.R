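## Cream-fraction regression from histogram features.
##
## The lead model is Gaussian-process regression with a rational quadratic
## kernel, a scale mixture of squared-exponential kernels
##   k(x, x') = sigma_f^2 * (1 + d^2 / (2 * alpha * ell^2))^(-alpha),
## d = ||x - x'||, which recovers the squared exponential as alpha -> Inf.
## Hyperparameters are fitted by maximizing the log marginal likelihood in
## log-space with random restarts; a constant basis (mean) function is used.
## Squared-exponential, Matern-5/2 and exponential GP kernels, ordinary
## linear regression and Gaussian/polynomial SVMs are available as
## comparison presets.

MODEL_VERSION <- "milkcv-model-1"

GP_FAMILIES <- c("rational_quadratic", "squared_exponential", "matern52",
                 "exponential")

#' Kernel specification
#'
#' @param family One of `"rational_quadratic"`, `"squared_exponential"`,
#'   `"matern52"`, `"exponential"` (Gaussian-process kernels), `"linear"`
#'   (ordinary least squares), `"gaussian_svm"` or `"polynomial_svm"`.
#' @param amplitude Signal variance `sigma_f^2` (> 0).
#' @param length_scale Kernel length scale `ell` (> 0).
#' @param alpha Rational-quadratic mixture parameter (> 0).
#' @param degree Polynomial degree (polynomial SVM / kernel value).
#' @param noise Observation noise variance (> 0; GP families).
#' @return A `kernel_spec` list.
#' @export
kernel_spec <- function(family = "rational_quadratic", amplitude = 1,
                        length_scale = 1, alpha = 1, degree = 3,
                        noise = 1e-2) {
  family <- match.arg(family, c(GP_FAMILIES, "linear", "polynomial",
                                "gaussian_svm", "polynomial_svm"))
  if (amplitude <= 0 || length_scale <= 0 || alpha <= 0 || noise <= 0)
    stop("kernel scale parameters must be positive")
  structure(list(family = family, amplitude = amplitude,
                 length_scale = length_scale, alpha = alpha,
                 degree = degree, noise = noise),
            class = "kernel_spec")
}

## Stationary kernel evaluated on a matrix/vector of Euclidean distances.
kernel_from_distance <- function(d, family, amplitude, length_scale, alpha) {
  switch(family,
    squared_exponential = amplitude * exp(-d^2 / (2 * length_scale^2)),
    rational_quadratic = amplitude *
      (1 + d^2 / (2 * alpha * length_scale^2))^(-alpha),
    exponential = amplitude * exp(-d / length_scale),
    matern52 = {
      r <- sqrt(5) * d / length_scale
      amplitude * (1 + r + r^2 / 3) * exp(-r)
    },
    stop("not a stationary kernel family: ", family))
}

#' Evaluate a kernel between two feature vectors
#'
#' @param spec A [kernel_spec()].
#' @param x,xp Numeric vectors of equal length.
#' @return Scalar kernel value.
#' @export
kernel_value <- function(spec, x, xp) {
  if (length(x) != length(xp)) stop("dimension mismatch between x and x'")
  if (spec$family %in% GP_FAMILIES) {
    d <- sqrt(sum((x - xp)^2))
    kernel_from_distance(d, spec$family, spec$amplitude, spec$length_scale,
                         spec$alpha)
  } else if (spec$family == "linear") {
    spec$amplitude * sum(x * xp)
  } else if (spec$family %in% c("polynomial", "polynomial_svm")) {
    spec$amplitude * (1 + sum(x * xp))^spec$degree
  } else {  # gaussian_svm shares the squared-exponential form
    spec$amplitude * exp(-sum((x - xp)^2) / (2 * spec$length_scale^2))
  }
}

## Pairwise Euclidean distance matrices, clamped at 0 for numerical safety.
dist_matrix <- function(x) {
  s <- rowSums(x^2)
  d2 <- outer(s, s, "+") - 2 * tcrossprod(x)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

cross_dist_matrix <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' Kernel (Gram) matrix of a feature matrix
#'
#' @param spec A [kernel_spec()] of a Gaussian-process family.
#' @param x Numeric matrix, one row per observation.
#' @return Symmetric positive semidefinite matrix `nrow(x) x nrow(x)`.
#' @export
kernel_matrix <- function(spec, x) {
  if (!spec$family %in% GP_FAMILIES)
    stop("kernel_matrix supports Gaussian-process kernel families")
  kernel_from_distance(dist_matrix(as.matrix(x)), spec$family,
                       spec$amplitude, spec$length_scale, spec$alpha)
}

#' Train/validation/test split
#'
#' Random permutation under the seed, then contiguous assignment by the
#' fractions: `floor(n * f)` rows for training and test, with leftover rows
#' assigned to validation (so `n = 100` gives 65/25/10 and `n = 10` gives
#' 6/3/1).
#'
#' @param n_rows Number of rows (>= 10).
#' @param fractions Train/validation/test fractions summing to 1;
#'   default `c(0.65, 0.25, 0.10)`.
#' @param seed Integer seed.
#' @return List with integer index vectors `train`, `validation`, `test`
#'   plus the `fractions` and `seed` used.
#' @export
split_dataset <- function(n_rows, fractions = c(0.65, 0.25, 0.10), seed = 1) {
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must be three numbers summing to 1")
  if (n_rows < 10) stop("need at least 10 rows to split")
  perm <- local({ set.seed(seed); sample.int(n_rows) })
  n_train <- floor(n_rows * fractions[1])
  n_test <- floor(n_rows * fractions[3])
  n_val <- n_rows - n_train - n_test
  list(train = sort(perm[seq_len(n_train)]),
       validation = sort(perm[n_train + seq_len(n_val)]),
       test = sort(perm[n_train + n_val + seq_len(n_test)]),
       fractions = fractions, seed = seed)
}

## Negative log marginal likelihood of a zero-mean GP on precomputed
## distances; theta is in log-space.
gp_neg_lml <- function(theta, d, y, family) {
  amplitude <- exp(theta[1]); length_scale <- exp(theta[2])
  noise <- exp(theta[3])
  alpha <- if (family == "rational_quadratic") exp(theta[4]) else 1
  n <- length(y)
  K <- kernel_from_distance(d, family, amplitude, length_scale, alpha)
  diag(K) <- diag(K) + noise
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) return(1e10)
  a <- backsolve(L, forwardsolve(t(L), y))
  as.numeric(0.5 * sum(y * a) + sum(log(diag(L))) + 0.5 * n * log(2 * pi))
}

chol_with_jitter <- function(K) {
  for (j in c(0, 1e-10, 1e-8, 1e-6, 1e-4)) {
    Kj <- K
    diag(Kj) <- diag(Kj) + j
    L <- tryCatch(chol(Kj), error = function(e) NULL)
    if (!is.null(L)) return(L)
  }
  stop("kernel matrix is singular even after jitter")
}

gp_fit <- function(x, y, spec, restarts, seed, optimize = TRUE) {
  d <- dist_matrix(x)
  y_mean <- mean(y)                  # constant basis function
  yc <- y - y_mean
  if (!optimize) {
    K <- kernel_from_distance(d, spec$family, spec$amplitude,
                              spec$length_scale, spec$alpha)
    diag(K) <- diag(K) + spec$noise
    L <- chol_with_jitter(K)
    alpha_vec <- backsolve(L, forwardsolve(t(L), yc))
    return(list(spec = spec, x_train = x, y_mean = y_mean,
                alpha_vec = alpha_vec, L = L,
                log_marginal_likelihood = NA_real_))
  }
  sd_y <- stats::sd(yc); if (!is.finite(sd_y) || sd_y == 0) sd_y <- 1
  med_d <- stats::median(d[upper.tri(d)])
  if (!is.finite(med_d) || med_d == 0) med_d <- 1
  has_alpha <- spec$family == "rational_quadratic"
  set.seed(seed)
  inits <- lapply(seq_len(max(1L, restarts)), function(i) {
    jit <- if (i == 1L) rep(0, 4) else stats::rnorm(4, 0, 1)
    th <- c(log(sd_y^2) + jit[1], log(med_d) + jit[2],
            log(0.1 * sd_y^2 + 1e-12) + jit[3])
    if (has_alpha) th <- c(th, 0 + jit[4])
    th
  })
  best <- NULL
  for (th0 in inits) {
    opt <- tryCatch(
      stats::optim(th0, gp_neg_lml, d = d, y = yc, family = spec$family,
                   method = "Nelder-Mead",
                   control = list(maxit = 400, reltol = 1e-8)),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
  }
  if (is.null(best)) stop("GP hyperparameter optimization failed")
  th <- best$par
  spec$amplitude <- exp(th[1]); spec$length_scale <- exp(th[2])
  spec$noise <- exp(th[3])
  if (has_alpha) spec$alpha <- exp(th[4])
  K <- kernel_from_distance(d, spec$family, spec$amplitude,
                            spec$length_scale, spec$alpha)
  diag(K) <- diag(K) + spec$noise
  L <- chol_with_jitter(K)
  alpha_vec <- backsolve(L, forwardsolve(t(L), yc))
  list(spec = spec, x_train = x, y_mean = y_mean, alpha_vec = alpha_vec,
       L = L, log_marginal_likelihood = -best$value)
}

#' Fit a cream-fraction regression model
#'
#' Gaussian-process families are fitted by maximizing the log marginal
#' likelihood (log-space Nelder-Mead with random restarts) with a constant
#' mean function; `"linear"` is ordinary least squares; the SVM presets use
#' epsilon-regression from \pkg{e1071}. Features are standardized with
#' training-set mean and standard deviation before kernel evaluation, and
#' the constants are stored in the model for reuse.
#'
#' @param features Data frame or matrix of features (a column named `c`, if
#'   present, is used as the target unless `targets` is given).
#' @param targets Numeric vector of cream fractions in `[0, 1]`.
#' @param spec A [kernel_spec()] naming the model family.
#' @param restarts Number of random restarts for GP hyperparameter search.
#' @param seed Integer seed for the restarts (recorded in the model).
#' @param optimize When `FALSE`, Gaussian-process families keep the
#'   hyperparameters given in `spec` instead of maximizing the marginal
#'   likelihood.
#' @return Object of class `cream_model`.
#' @export
fit_cream_model <- function(features, targets = NULL,
                            spec = kernel_spec("rational_quadratic"),
                            restarts = 3, seed = 1, optimize = TRUE) {
  if (is.data.frame(features) && is.null(targets) && "c" %in% names(features)) {
    targets <- features$c
    features <- features[setdiff(names(features), "c")]
  }
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  y <- as.numeric(targets)
  if (nrow(x) < 2L) stop("need at least 2 training rows")
  if (anyNA(y) || any(y < 0) || any(y > 1))
    stop("targets must be cream fractions in [0, 1]")
  mu <- colMeans(x)
  sdev <- apply(x, 2, stats::sd)
  sdev[!is.finite(sdev) | sdev == 0] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sdev, "/")
  fitted <- if (spec$family %in% GP_FAMILIES) {
    gp_fit(xs, y, spec, restarts, seed, optimize = optimize)
  } else if (spec$family == "linear") {
    qrX <- qr(cbind(1, xs))
    beta <- qr.coef(qrX, y)
    beta[is.na(beta)] <- 0
    list(spec = spec, beta = beta)
  } else if (spec$family %in% c("gaussian_svm", "polynomial_svm")) {
    kern <- if (spec$family == "gaussian_svm") "radial" else "polynomial"
    svm_fit <- e1071::svm(xs, y, type = "eps-regression", kernel = kern,
                          degree = spec$degree, scale = FALSE)
    list(spec = spec, svm = svm_fit)
  } else stop("unsupported model family: ", spec$family)
  structure(c(fitted,
              list(family = spec$family, version = MODEL_VERSION,
                   feature_names = colnames(x), mu = mu, sdev = sdev,
                   seed = seed)),
            class = "cream_model")
}

#' Predict cream fractions from a fitted model
#'
#' @param object A `cream_model`.
#' @param newdata Data frame or matrix of features with the training
#'   dimensionality (a `c` column, if present, is ignored).
#' @param se.fit If `TRUE` (Gaussian-process families only) also return the
#'   predictive standard deviation of the latent function.
#' @param ... Unused.
#' @return Numeric vector of predictions, or a list with `fit` and `se.fit`
#'   when `se.fit = TRUE`.
#' @export
predict.cream_model <- function(object, newdata, se.fit = FALSE, ...) {
  if (is.data.frame(newdata) && "c" %in% names(newdata))
    newdata <- newdata[setdiff(names(newdata), "c")]
  x <- as.matrix(newdata)
  storage.mode(x) <- "double"
  if (ncol(x) != length(object$mu))
    stop("feature dimension mismatch: model expects ", length(object$mu),
         " features, got ", ncol(x))
  xs <- sweep(sweep(x, 2, object$mu), 2, object$sdev, "/")
  if (object$family %in% GP_FAMILIES) {
    sp <- object$spec
    dcross <- cross_dist_matrix(xs, object$x_train)
    ks <- kernel_from_distance(dcross, sp$family, sp$amplitude,
                               sp$length_scale, sp$alpha)
    mean_pred <- object$y_mean + as.numeric(ks %*% object$alpha_vec)
    if (!se.fit) return(mean_pred)
    v <- forwardsolve(t(object$L), t(ks))
    var_pred <- pmax(sp$amplitude - colSums(v^2), 0)
    list(fit = mean_pred, se.fit = sqrt(var_pred))
  } else if (object$family == "linear") {
    pred <- as.numeric(cbind(1, xs) %*% object$beta)
    if (se.fit) stop("se.fit is only available for Gaussian-process families")
    pred
  } else {
    if (se.fit) stop("se.fit is only available for Gaussian-process families")
    as.numeric(stats::predict(object$svm, xs))
  }
}

#' Evaluation metrics for cream-fraction predictions
#'
#' Coefficient of determination `R2 = 1 - SSE/SST`, mean absolute error,
#' root mean squared error, mean relative error in percent (over strictly
#' positive truths), mean bias, and the two-sided paired t-test p-value
#' comparing the two series.
#'
#' @param pred,truth Numeric vectors of equal length (>= 2).
#' @return List of class `eval_report` with `r2`, `mae`, `rmse`, `mre`,
#'   `mean_bias`, `paired_p`, `n`.
#' @export
evaluate_predictions <- function(pred, truth) {
  if (length(pred) != length(truth) || length(pred) < 2L)
    stop("pred and truth must have equal length >= 2")
  sst <- sum((truth - mean(truth))^2)
  if (sst == 0) stop("R2 undefined: truth has zero variance")
  err <- pred - truth
  pos <- truth > 0
  paired_p <- tryCatch(stats::t.test(pred, truth, paired = TRUE)$p.value,
                       error = function(e) NA_real_)
  structure(list(
    r2 = 1 - sum(err^2) / sst,
    mae = mean(abs(err)),
    rmse = sqrt(mean(err^2)),
    mre = if (any(pos)) mean(100 * abs(err[pos]) / truth[pos]) else NA_real_,
    mean_bias = mean(err),
    paired_p = paired_p,
    n = length(pred)), class = "eval_report")
}

#' Permutation feature importance
#'
#' Importance of each feature as the drop in validation R2 when that column
#' is randomly shuffled (one seeded permutation per feature); a
#' model-agnostic substitute for attribution methods.
#'
#' @param model A fitted `cream_model`.
#' @param features Validation feature table (>= 10 rows).
#' @param targets Validation cream fractions.
#' @param seed Integer seed; the ranking is deterministic per seed.
#' @return Data frame with columns `feature` and `importance`, sorted in
#'   decreasing importance.
#' @export
permutation_importance <- function(model, features, targets, seed = 1) {
  if (is.data.frame(features) && "c" %in% names(features))
    features <- features[setdiff(names(features), "c")]
  x <- as.matrix(features)
  if (nrow(x) < 10L) stop("need at least 10 validation rows")
  base_r2 <- evaluate_predictions(predict(model, x), targets)$r2
  set.seed(seed)
  perms <- replicate(ncol(x), sample.int(nrow(x)), simplify = FALSE)
  imp <- vapply(seq_len(ncol(x)), function(j) {
    xp <- x
    xp[, j] <- x[perms[[j]], j]
    base_r2 - evaluate_predictions(predict(model, xp), targets)$r2
  }, numeric(1))
  out <- data.frame(feature = colnames(x), importance = imp)
  out[order(-out$importance), , drop = FALSE]
}

#' Save / load a fitted model
#'
#' Single-file serialization carrying the kernel specification,
#' standardization constants, training statistics and seed, tagged with a
#' format version; loading a mismatched version is refused. Reloaded models
#' produce bit-identical predictions.
#'
#' @param model A `cream_model`.
#' @param path File path.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, "cream_model")) stop("not a cream_model")
  saveRDS(model, path, version = 3)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!identical(model$version, MODEL_VERSION))
    stop("model file version '", model$version,
         "' does not match supported version '", MODEL_VERSION, "'")
  model
}
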