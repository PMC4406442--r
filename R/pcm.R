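# Proteochemometric modelling: descriptor assembly, SVR under four
# kernels, 10-fold cross-validation, and the QSAR evaluation statistics.

#' Kernel specification
#'
#' Four kernels are supported:
#' * `normalized_poly`: `((x.y) + c)^d / sqrt(((x.x) + c)^d ((y.y) + c)^d)`
#'   (defaults `d = 2`, `c = 0`),
#' * `polynomial`: `((x.y) + c)^d` (defaults `d = 1`, `c = 1`),
#' * `puk`: the Pearson VII universal kernel
#'   `1 / (1 + (2 |x - y| sqrt(2^(1/omega) - 1) / sigma)^2)^omega`
#'   (defaults `omega = 1`, `sigma = 1`),
#' * `rbf`: `exp(-gamma |x - y|^2)` (default `gamma = 0.01`).
#'
#' @param kind one of `"normalized_poly"`, `"polynomial"`, `"puk"`,
#'   `"rbf"`.
#' @param d,c polynomial exponent and constant.
#' @param omega,sigma Pearson VII shape and width (positive).
#' @param gamma RBF width (positive).
#' @return a `kernel_spec` list.
#' @export
kernel_spec <- function(kind = c("normalized_poly", "polynomial", "puk",
                                 "rbf"),
                        d = NULL, c = NULL, omega = 1, sigma = 1,
                        gamma = 0.01) {
  kind <- match.arg(kind)
  if (is.null(d)) d <- if (kind == "normalized_poly") 2 else 1
  if (is.null(c)) c <- if (kind == "normalized_poly") 0 else 1
  if (kind == "puk" && (omega <= 0 || sigma <= 0))
    stop("puk needs positive omega and sigma")
  if (kind == "rbf" && gamma <= 0) stop("rbf needs positive gamma")
  structure(list(kind = kind, d = d, c = c, omega = omega, sigma = sigma,
                 gamma = gamma),
            class = "kernel_spec")
}

#' Evaluate a kernel on two vectors
#'
#' @param spec a [kernel_spec()].
#' @param x,y numeric vectors of equal length.
#' @return scalar kernel value.
#' @export
kernel_eval <- function(spec, x, y) {
  if (length(x) != length(y)) stop("vector lengths differ")
  drop(kernel_matrix(spec, rbind(x), rbind(y)))
}

#' Kernel (Gram) matrix between two row sets
#'
#' @param spec a [kernel_spec()].
#' @param X numeric matrix (n x p).
#' @param Y numeric matrix (m x p); defaults to `X`.
#' @return numeric n x m matrix.
#' @export
kernel_matrix <- function(spec, X, Y = X) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  G <- tcrossprod(X, Y)
  switch(spec$kind,
    polynomial = (G + spec$c)^spec$d,
    normalized_poly = {
      dx <- (rowSums(X^2) + spec$c)^spec$d
      dy <- (rowSums(Y^2) + spec$c)^spec$d
      (G + spec$c)^spec$d / sqrt(outer(dx, dy))
    },
    rbf = {
      d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * G
      exp(-spec$gamma * pmax(d2, 0))
    },
    puk = {
      d2 <- pmax(outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * G, 0)
      f <- 2 * sqrt(2^(1 / spec$omega) - 1) / spec$sigma
      1 / (1 + f^2 * d2)^spec$omega
    })
}

#' Assemble a PCM dataset from descriptor tables
#'
#' Concatenates descriptor blocks column-wise according to a named recipe.
#' Recipes follow the `Fab-Fag[-EPIF|-MLPD]` naming: `Fab`/`Fag` the
#' antibody/antigen protein fingerprints, `EPIF` the interaction
#' fingerprint, `MLPD` the outer-product cross-term, `Sab`/`Sag` sequence
#' similarity and `Gab`/`Gag` geometry descriptors. Column names carry
#' their block as a prefix.
#'
#' @param tables named list of numeric matrices (rows = complexes, aligned
#'   row names = complex ids).
#' @param recipe recipe string, e.g. `"Fab-Fag-EPIF"`; each dash-separated
#'   component must be a name in `tables`.
#' @param y numeric vector of affinity labels aligned with the rows.
#' @param split optional logical vector (`TRUE` = training row); default
#'   all training.
#' @return a `pcm_dataset`: list with `ids`, `X`, `y`, `split`, `layout`.
#' @export
assemble_features <- function(tables, recipe, y, split = NULL) {
  parts <- strsplit(recipe, "-", fixed = TRUE)[[1]]
  missing_parts <- setdiff(parts, names(tables))
  if (length(missing_parts) > 0)
    stop("recipe component(s) not in tables: ",
         paste(missing_parts, collapse = ", "))
  ids <- rownames(tables[[parts[1]]])
  if (is.null(ids) || anyDuplicated(ids))
    stop("tables must carry unique complex ids as row names")
  blocks <- lapply(parts, function(p) {
    m <- tables[[p]]
    if (!setequal(rownames(m), ids)) stop("complex ids differ across tables")
    m <- m[ids, , drop = FALSE]
    colnames(m) <- paste0(p, ".", if (is.null(colnames(m)))
      seq_len(ncol(m)) else colnames(m))
    m
  })
  X <- do.call(cbind, blocks)
  if (length(y) != nrow(X)) stop("labels do not match rows")
  if (is.null(split)) split <- rep(TRUE, nrow(X))
  sizes <- vapply(blocks, ncol, integer(1))
  ends <- cumsum(sizes)
  layout <- stats::setNames(
    lapply(seq_along(parts),
           function(i) (ends[i] - sizes[i] + 1):ends[i]), parts)
  structure(list(ids = ids, X = X, y = as.numeric(y), split = split,
                 layout = layout, recipe = recipe),
            class = "pcm_dataset")
}

#' @export
print.pcm_dataset <- function(x, ...) {
  cat("PCM dataset [", x$recipe, "]: ", nrow(x$X), " complexes x ",
      ncol(x$X), " features (", sum(x$split), " train / ",
      sum(!x$split), " test)\n", sep = "")
  invisible(x)
}

standardizer <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd == 0 | is.na(sd)] <- 1
  list(mu = mu, sd = sd)
}

apply_standardizer <- function(X, st) {
  sweep(sweep(X, 2, st$mu), 2, st$sd, "/")
}

#' Train epsilon-SVR with a precomputed kernel
#'
#' Fits support vector regression (kernlab's SMO-type `eps-svr`) on the
#' Gram matrix of the requested kernel. Features are standardized to
#' training-set mean/variance before kernel evaluation by default (the
#' descriptor blocks mix counts, AAindex values and percent identities);
#' labels are internally centered and scaled for the solver and predictions
#' are returned on the original scale. Training is deterministic given the
#' data and parameters.
#'
#' @param X numeric training feature matrix.
#' @param y numeric training labels.
#' @param spec a [kernel_spec()].
#' @param cost regularization constant C (default 1).
#' @param epsilon insensitivity tube (default 1e-3).
#' @param standardize standardize features first (default TRUE).
#' @return an `svr_model`; predict with [predict.svr_model()].
#' @export
train_svr <- function(X, y, spec = kernel_spec(), cost = 1.0,
                      epsilon = 1e-3, standardize = TRUE) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 training rows")
  st <- if (standardize) standardizer(X) else NULL
  Xs <- if (standardize) apply_standardizer(X, st) else X
  y_mu <- mean(y); y_sd <- stats::sd(y)
  model <- NULL
  if (!is.finite(y_sd) || y_sd == 0) {
    warning("labels have zero variance; returning a constant predictor")
    y_sd <- 1
  } else {
    K <- kernel_matrix(spec, Xs)
    model <- kernlab::ksvm(kernlab::as.kernelMatrix(K),
                           (y - y_mu) / y_sd, type = "eps-svr",
                           C = cost, epsilon = epsilon)
  }
  structure(list(model = model, X_train = Xs, spec = spec, st = st,
                 y_mu = y_mu, y_sd = y_sd, cost = cost, epsilon = epsilon),
            class = "svr_model")
}

#' Predict from a fitted SVR model
#'
#' @param object an `svr_model`.
#' @param newdata numeric feature matrix with the training columns.
#' @param ... unused.
#' @return numeric vector of predicted affinities.
#' @method predict svr_model
#' @export
predict.svr_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (is.null(object$model)) return(rep(object$y_mu, nrow(newdata)))
  Xs <- if (!is.null(object$st)) apply_standardizer(newdata, object$st)
        else newdata
  K <- kernel_matrix(object$spec, Xs, object$X_train)
  sv <- kernlab::SVindex(object$model)
  p <- kernlab::predict(object$model,
                        kernlab::as.kernelMatrix(K[, sv, drop = FALSE]))
  as.numeric(p) * object$y_sd + object$y_mu
}

#' Predictive squared correlation Q2
#'
#' `1 - sum((pred - obs)^2) / sum((obs - ref_mean)^2)`; `ref_mean` defaults
#' to the mean of `obs`.
#'
#' @param pred,obs numeric vectors.
#' @param ref_mean reference mean for the denominator.
#' @return scalar Q2 (can be negative).
#' @export
q_squared <- function(pred, obs, ref_mean = mean(obs)) {
  1 - sum((pred - obs)^2) / sum((obs - ref_mean)^2)
}

#' k-fold cross-validated Q2
#'
#' Rows are shuffled once with `seed`, split into `k` near-equal folds,
#' and each fold is predicted by a model trained on the others. Q2cv is
#' computed over the pooled out-of-fold predictions against the mean of
#' all labels. The same seed always yields the same folds and the same
#' Q2cv.
#'
#' @param X,y training features and labels.
#' @param spec a [kernel_spec()].
#' @param k number of folds (default 10).
#' @param seed integer RNG seed for the fold shuffle.
#' @param ... passed to [train_svr()].
#' @return list with `q2cv`, `pred` (out-of-fold predictions in row
#'   order) and `folds` (fold id per row).
#' @export
cross_validate <- function(X, y, spec = kernel_spec(), k = 10, seed = 1,
                           ...) {
  n <- nrow(X)
  if (k < 2) stop("k must be at least 2")
  if (k > n) stop("more folds than rows")
  ord <- with_seed(seed, sample.int(n))
  fold <- integer(n)
  fold[ord] <- rep_len(seq_len(k), n)
  pred <- numeric(n)
  for (f in seq_len(k)) {
    hold <- fold == f
    m <- train_svr(X[!hold, , drop = FALSE], y[!hold], spec, ...)
    pred[hold] <- predict(m, X[hold, , drop = FALSE])
  }
  list(q2cv = q_squared(pred, y), pred = pred, folds = fold)
}

#' QSAR error statistics for a prediction set
#'
#' Computes mean absolute error, root mean squared error, relative
#' absolute error and root relative squared error (the latter two as
#' percentages, relative to the mean-of-observed reference predictor),
#' plus Q2. With constant observed labels RAE/RRSE are undefined and
#' returned as `NA`.
#'
#' @param pred,obs numeric vectors of predicted and observed affinities.
#' @return named list: `MAE`, `RMSE` (label units), `RAE`, `RRSE`
#'   (percent), `Q2`.
#' @export
pcm_metrics <- function(pred, obs) {
  e <- pred - obs
  dev <- obs - mean(obs)
  abs_dev <- sum(abs(dev)); sq_dev <- sum(dev^2)
  list(
    MAE = mean(abs(e)),
    RMSE = sqrt(mean(e^2)),
    RAE = if (abs_dev > 0) 100 * sum(abs(e)) / abs_dev else NA_real_,
    RRSE = if (sq_dev > 0) 100 * sqrt(sum(e^2) / sq_dev) else NA_real_,
    Q2 = if (sq_dev > 0) 1 - sum(e^2) / sq_dev else NA_real_
  )
}

#' Fit, cross-validate and evaluate one PCM model
#'
#' Trains on the dataset's training rows, reports goodness of fit on the
#' training set (`R2`: squared Pearson correlation of fitted vs observed;
#' plus `Q2cv` from k-fold cross-validation) and predictive ability on the
#' held-out rows (`Q2test`, MAE, RMSE, RAE, RRSE).
#'
#' @param dataset a `pcm_dataset` from [assemble_features()] or
#'   [make_pcm_dataset()].
#' @param spec a [kernel_spec()].
#' @param folds cross-validation folds (default 10; 0 skips CV).
#' @param seed fold-shuffle seed.
#' @param ... passed to [train_svr()].
#' @return a `model_report` list: `recipe`, `kernel`, `n_train`, `n_test`,
#'   `R2`, `Q2cv`, `Q2test`, `MAE`, `RMSE`, `RAE`, `RRSE`, and the fitted
#'   `model`.
#' @export
run_pcm <- function(dataset, spec = kernel_spec(), folds = 10, seed = 1,
                    ...) {
  tr <- dataset$split
  Xtr <- dataset$X[tr, , drop = FALSE]; ytr <- dataset$y[tr]
  model <- train_svr(Xtr, ytr, spec, ...)
  p_tr <- predict(model, Xtr)
  r2 <- if (stats::sd(p_tr) > 0 && stats::sd(ytr) > 0)
    stats::cor(p_tr, ytr)^2 else NA_real_
  q2cv <- if (folds >= 2)
    cross_validate(Xtr, ytr, spec, k = folds, seed = seed, ...)$q2cv
    else NA_real_

  rep <- list(recipe = dataset$recipe, kernel = spec$kind,
              n_train = sum(tr), n_test = sum(!tr), R2 = r2, Q2cv = q2cv,
              Q2test = NA_real_, MAE = NA_real_, RMSE = NA_real_,
              RAE = NA_real_, RRSE = NA_real_, model = model)
  if (any(!tr)) {
    p_te <- predict(model, dataset$X[!tr, , drop = FALSE])
    m <- pcm_metrics(p_te, dataset$y[!tr])
    rep[c("MAE", "RMSE", "RAE", "RRSE", "Q2test")] <-
      m[c("MAE", "RMSE", "RAE", "RRSE", "Q2")]
  }
  class(rep) <- "model_report"
  rep
}

#' @export
print.model_report <- function(x, ...) {
  cat("PCM model report [", x$recipe, ", ", x$kernel, " kernel]\n",
      sep = "")
  cat(sprintf("  n = %d train / %d test\n", x$n_train, x$n_test))
  cat(sprintf("  R2 = %.3f   Q2cv = %.3f   Q2test = %.3f\n",
              x$R2, x$Q2cv, x$Q2test))
  cat(sprintf("  MAE = %.3f  RMSE = %.3f  RAE = %.2f%%  RRSE = %.2f%%\n",
              x$MAE, x$RMSE, x$RAE, x$RRSE))
  invisible(x)
}

#' Write a model report as JSON
#'
#' @param report a `model_report`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  keep <- setdiff(names(report), "model")
  jsonlite::write_json(report[keep], path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
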