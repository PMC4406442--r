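# Kernels, SVR training, cross-validation, metrics, feature assembly.

# direct scalar formula evaluation, independent of the vectorized code
direct_kernel <- function(spec, x, y) {
  dot <- function(u, v) sum(u * v)
  nrm2 <- sum((x - y)^2)
  switch(spec$kind,
    polynomial = (dot(x, y) + spec$c)^spec$d,
    normalized_poly = (dot(x, y) + spec$c)^spec$d /
      sqrt((dot(x, x) + spec$c)^spec$d * (dot(y, y) + spec$c)^spec$d),
    rbf = exp(-spec$gamma * nrm2),
    puk = 1 / (1 + (2 * sqrt(nrm2) * sqrt(2^(1 / spec$omega) - 1) /
                      spec$sigma)^2)^spec$omega)
}

test_that("kernel values match direct formula evaluation", {
  set.seed(109)
  specs <- list(kernel_spec("normalized_poly"), kernel_spec("polynomial"),
                kernel_spec("puk"), kernel_spec("rbf"))
  for (spec in specs) {
    for (rep in 1:20) {
      x <- rnorm(12); y <- rnorm(12)
      expect_equal(kernel_eval(spec, x, y), direct_kernel(spec, x, y),
                   tolerance = 1e-12)
      # symmetry
      expect_equal(kernel_eval(spec, x, y), kernel_eval(spec, y, x),
                   tolerance = 1e-12)
    }
    # self-similarity of the normalized kernels
    x <- rnorm(12)
    if (spec$kind != "polynomial")
      expect_equal(kernel_eval(spec, x, x), 1, tolerance = 1e-12)
  }
  expect_error(kernel_eval(kernel_spec("rbf"), 1:3, 1:4), "length")
  expect_error(kernel_spec("puk", omega = -1), "positive")
  expect_error(kernel_spec("rbf", gamma = 0), "positive")
})

test_that("Gram matrices are symmetric PSD and normalized kernels bounded", {
  set.seed(113)
  X <- matrix(rnorm(20 * 6), 20, 6)
  for (kind in c("normalized_poly", "polynomial", "puk", "rbf")) {
    K <- kernel_matrix(kernel_spec(kind), X)
    expect_equal(K, t(K), tolerance = 1e-12)
    expect_gte(min(eigen(K, symmetric = TRUE,
                         only.values = TRUE)$values), -1e-8)
    if (kind != "polynomial")
      expect_true(all(K > 0 & K <= 1 + 1e-12))
  }
})

test_that("error statistics match hand arithmetic and the closed-form
           limits", {
  t <- c(1, 2, 4)
  # perfect predictor
  m0 <- pcm_metrics(t, t)
  expect_equal(m0$MAE, 0); expect_equal(m0$RMSE, 0)
  expect_equal(m0$RAE, 0); expect_equal(m0$RRSE, 0)
  expect_equal(m0$Q2, 1)
  # constant mean predictor
  mm <- pcm_metrics(rep(mean(t), 3), t)
  expect_equal(mm$RAE, 100); expect_equal(mm$RRSE, 100)
  expect_equal(mm$Q2, 0)
  # hand-evaluated case: p = (1,2,3), t = (1,2,4)
  m <- pcm_metrics(c(1, 2, 3), t)
  expect_equal(m$MAE, 1 / 3)
  expect_equal(m$RMSE, sqrt(1 / 3))
  expect_equal(m$RAE, 100 * 1 / (10 / 3))
  expect_equal(m$RRSE, 100 * sqrt(1 / (14 / 3)))
  expect_equal(m$Q2, 1 - 3 / 14)
  # MAE <= RMSE always
  set.seed(127)
  for (rep in 1:20) {
    p <- rnorm(15); tt <- rnorm(15)
    mr <- pcm_metrics(p, tt)
    expect_lte(mr$MAE, mr$RMSE + 1e-12)
    expect_gte(mr$RAE, 0); expect_gte(mr$RRSE, 0)
  }
  # constant observed labels -> undefined relative errors
  mc <- pcm_metrics(c(1, 2), c(3, 3))
  expect_true(is.na(mc$RAE) && is.na(mc$RRSE))
})

test_that("SVR fits realizable data and degrades gracefully", {
  set.seed(131)
  X <- matrix(rnorm(60 * 5), 60, 5)
  y <- as.vector(X %*% c(2, -1, 0, 0.5, 1)) + 3
  m <- train_svr(X, y, kernel_spec("polynomial", d = 1, c = 1), cost = 100)
  expect_lt(max(abs(predict(m, X) - y)), 0.05)

  expect_warning(mc <- train_svr(X[1:10, ], rep(2, 10)), "zero variance")
  expect_equal(predict(mc, X[11:20, ]), rep(2, 10))
  expect_error(train_svr(X[1, , drop = FALSE], 1), "at least 2")
})

test_that("cross-validation is seed-deterministic and detects signal vs
           permutation null", {
  ds <- make_pcm_dataset(pcm_recipe(seed = 11, n_samples = 80,
                                    noise_sd = 0))
  tr <- ds$split
  X <- ds$X[tr, , drop = FALSE]; y <- ds$y[tr]
  spec <- kernel_spec("polynomial", d = 1, c = 1)
  a <- cross_validate(X, y, spec, k = 10, seed = 5, cost = 10)
  b <- cross_validate(X, y, spec, k = 10, seed = 5, cost = 10)
  expect_identical(a, b)
  expect_gt(a$q2cv, 0.5)
  expect_equal(sort(unique(a$folds)), 1:10)
  expect_true(max(table(a$folds)) - min(table(a$folds)) <= 1)

  # permutation null: labels shuffled against features
  set.seed(137)
  null_q2 <- replicate(10, {
    yp <- sample(y)
    cross_validate(X, yp, spec, k = 5, seed = 1, cost = 10)$q2cv
  })
  expect_lte(mean(null_q2), 0)
  expect_error(cross_validate(X, y, spec, k = 1), "at least 2")
  expect_error(cross_validate(X[1:4, ], y[1:4], spec, k = 10),
               "more folds")
})

test_that("feature assembly concatenates blocks with the declared widths", {
  ds <- make_pcm_dataset(pcm_recipe(seed = 3, n_samples = 20))
  tb <- ds$tables
  y <- ds$y
  expect_equal(ncol(assemble_features(tb, "Fab-Fag", y)$X), 220)
  expect_equal(ncol(assemble_features(tb, "Fab-Fag-EPIF", y)$X), 370)
  expect_equal(ncol(assemble_features(tb, "Fab-Fag-MLPD", y)$X),
               220 + 12100)
  d3 <- assemble_features(tb, "Fab-Fag-EPIF", y)
  expect_equal(d3$layout$EPIF, 221:370)
  expect_true(all(startsWith(colnames(d3$X)[d3$layout$Fab], "Fab.")))
  expect_error(assemble_features(tb, "Fab-Sag", y), "not in tables")
  expect_error(assemble_features(tb, "Fab-Fag", y[1:5]), "labels")
})

test_that("run_pcm reports fit, cross-validated and held-out statistics", {
  ds <- make_pcm_dataset(pcm_recipe(seed = 19, n_samples = 100,
                                    noise_sd = 0.2))
  rep <- run_pcm(ds, kernel_spec("polynomial", d = 1, c = 1), folds = 5,
                 seed = 2, cost = 10)
  expect_equal(rep$n_train, 80)
  expect_equal(rep$n_test, 20)
  expect_true(rep$R2 > 0.9 && rep$R2 <= 1)
  expect_true(is.finite(rep$Q2cv) && is.finite(rep$Q2test))
  expect_lte(rep$MAE, rep$RMSE)
  expect_output(print(rep), "PCM model report")

  f <- tempfile(fileext = ".json")
  write_report_json(rep, f)
  parsed <- jsonlite::read_json(f)
  expect_equal(parsed$recipe, "Fab-Fag")
  expect_equal(parsed$Q2test, rep$Q2test, tolerance = 1e-9)
})
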