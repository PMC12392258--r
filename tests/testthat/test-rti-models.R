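test_that("fingerprint-stratified split partitions and reproduces", {
  w <- cached_world("split", n_compounds = 40, spectra_per_compound = 2,
                    seed = 2)
  sp <- split_by_fingerprint_strata(w$compounds, fraction = 0.7, seed = 9)
  expect_equal(nrow(sp$train) + nrow(sp$test), nrow(w$compounds))
  expect_gt(nrow(sp$train), 0)
  expect_gt(nrow(sp$test), 0)
  expect_equal(sort(c(sp$train$inchikey, sp$test$inchikey)),
               sort(w$compounds$inchikey))
  sp2 <- split_by_fingerprint_strata(w$compounds, fraction = 0.7, seed = 9)
  expect_identical(sp$train$inchikey, sp2$train$inchikey)
  expect_equal(nrow(sp$train) / nrow(w$compounds), 0.7, tolerance = 0.15)
  expect_error(split_by_fingerprint_strata(w$compounds[1, ], 0.7), "at least 2")
})

test_that("leverage split is deterministic and spans the leverage range", {
  set.seed(4)
  X <- matrix(rnorm(10 * 3), 10, 3)
  sp <- split_by_leverage(X, fraction = 0.7)
  expect_equal(length(sp$train_idx), 7L)
  expect_equal(length(sp$test_idx), 3L)
  expect_equal(sort(c(sp$train_idx, sp$test_idx)), 1:10)
  expect_identical(sp, split_by_leverage(X, fraction = 0.7))

  X2 <- matrix(rnorm(60 * 4), 60, 4)
  sp2 <- split_by_leverage(X2, fraction = 0.7)
  h <- leverage(suppressWarnings(fit_ad(X2)), X2)
  expect_gte(max(h[sp2$test_idx]), stats::median(h))
  expect_warning(split_by_leverage(matrix(rnorm(8), 2, 4), 0.5), "pseudo")
})

test_that("retention forests reproduce under a seed and fit constants", {
  set.seed(6)
  X <- matrix(rbinom(30 * 8, 1, 0.5), 30, 8)
  m_const <- train_rti(X, rep(55, 30), "cnl", seed = 1)
  expect_equal(predict_rti(m_const, X)$rti, rep(55, 30))

  y <- rnorm(30, 500, 100)
  m1 <- train_rti(X, y, "cnl", seed = 3)
  m2 <- train_rti(X, y, "cnl", seed = 3)
  expect_identical(predict_rti(m1, X)$rti, predict_rti(m2, X)$rti)
  expect_error(train_rti(X, c(y[-1], NA), "cnl"), "finite")
  expect_error(train_rti(X[1:5, ], y[1:5], "cnl"), "at least 10")
})

test_that("a noiseless linear structure-retention law is recovered", {
  # forests interpolate additive laws only where the design is densely
  # sampled, so the recovery check uses few continuous descriptors and
  # bagging (mtry = p)
  set.seed(8)
  n <- 500
  p <- 5
  X <- matrix(runif(n * p), n, p)
  wts <- runif(p, 50, 150)
  y <- as.numeric(X %*% wts)
  idx <- sample(n, 350)
  m <- train_rti(X[idx, ], y[idx], "fingerprint", seed = 8, mtry = p)
  ev <- evaluate_regression(y[-idx], predict_rti(m, X[-idx, ])$rti)
  expect_gte(ev$r2, 0.9)
})

test_that("predictions carry applicability-domain flags", {
  set.seed(10)
  X <- matrix(rnorm(80 * 5, 10, 2), 80, 5)
  y <- rowSums(X) + rnorm(80)
  m <- train_rti(X, y, "cnl", seed = 1)
  pr <- predict_rti(m, X)
  expect_true(all(is.finite(pr$rti)))
  expect_gte(mean(pr$in_domain), 0.95)
  far <- predict_rti(m, X[1, , drop = FALSE] * 100)
  expect_false(far$in_domain)
  expect_error(predict_rti(m, matrix(0, 1, 4)), "expects")
})

test_that("regression metrics match hand-computed and brute-force values", {
  perfect <- evaluate_regression(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unlist(perfect[c("rmse", "mae", "mre")]), c(rmse = 0, mae = 0, mre = 0))
  expect_equal(perfect$r2, 1)

  ev <- evaluate_regression(c(100, 200), c(110, 190))
  expect_equal(ev$rmse, 10)
  expect_equal(ev$mae, 10)
  expect_equal(ev$mre, 7.5)
  expect_equal(ev$r2, 1 - 200 / 5000)

  expect_error(evaluate_regression(c(0, 0), c(1, 1)), "MRE")
  expect_error(evaluate_regression(1:3, 1:2), "length")

  set.seed(12)
  for (rep in 1:25) {
    n <- sample(2:60, 1)
    y <- rnorm(n, 100, 40)
    yh <- y + rnorm(n, 0, 15)
    ev <- evaluate_regression(y, yh)
    expect_equal(ev$rmse, sqrt(sum((y - yh)^2) / n), tolerance = 1e-10)
    expect_equal(ev$mae, sum(abs(y - yh)) / n, tolerance = 1e-10)
    expect_equal(ev$mre, sum(abs((y - yh) / y)) / n * 100, tolerance = 1e-10)
    expect_equal(ev$r2, 1 - sum((y - yh)^2) / sum((y - mean(y))^2),
                 tolerance = 1e-10)
  }
})

test_that("fingerprint and CNL retention estimates are exchangeable", {
  # both models learn the same latent retention variable, so on spectra
  # held out from the CNL fit the two predictions differ by noise-level
  # amounts centered on zero (no systematic offset between the models)
  w <- cached_world("exchange", n_compounds = 300, spectra_per_compound = 3,
                    noise = list(mz_sd = 0.001, intensity_sd = 0.2,
                                 rti_sd = 25, dropout = 0.1),
                    seed = 14)
  first <- !duplicated(w$spectra$compound_id)
  feats <- cnl_features(w$spectra, w$moi, drop_below_min = FALSE)
  X <- cnl_design_matrix(feats)
  y <- w$compounds$true_rti[match(w$spectra$compound_id, w$compounds$inchikey)]
  m_cnl <- train_rti(X[!first, ], y[!first], "cnl", seed = 14)
  m_mf <- train_rti(w$compounds$fp, w$compounds$true_rti,
                    "fingerprint", seed = 14)

  rti_cnl <- predict_rti(m_cnl, X[first, ])$rti
  fp_held <- w$compounds$fp[match(w$spectra$compound_id[first],
                                  w$compounds$inchikey), ]
  rti_mf <- predict_rti(m_mf, fp_held)$rti
  diff <- rti_mf - rti_cnl
  expect_lt(abs(mean(diff)), w$noise$rti_sd)
  expect_lt(abs(mean(diff)), 0.05 * diff(range(y)))
})

test_that("tidy and glance expose importance and fit metadata", {
  set.seed(16)
  X <- matrix(rnorm(60 * 4), 60, 4, dimnames = list(NULL, paste0("v", 1:4)))
  y <- 3 * X[, 1] + rnorm(60, 0, 0.1)
  m <- train_rti(X, y, "cnl", seed = 2)
  td <- tidy(m)
  expect_equal(sort(td$feature), sort(paste0("v", 1:4)))
  expect_equal(td$feature[1], "v1")  # dominant predictor ranks first
  gl <- glance(m)
  expect_equal(gl$n, 60)
  expect_equal(gl$p, 4)
  expect_s3_class(autoplot(m, X, y), "ggplot")
})
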