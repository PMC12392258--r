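test_that("retention-index error is the signed model difference", {
  expect_equal(rti_error(500, 450), 50)
  expect_equal(rti_error(123.4, 123.4), 0)
  set.seed(1)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(rti_error(a, b), -rti_error(b, a))
})

test_that("decoy pairing never reproduces the true identity", {
  compounds <- tibble::tibble(inchikey = c("A-A-N", "B-B-N", "C-C-N"),
                              monoisotopic_mass = c(200, 200, 350))
  spectra <- make_spec("s1", 201, mz = 100, compound_id = "A-A-N")
  spectra <- dplyr::bind_rows(
    spectra, make_spec("s2", 201, mz = 110, compound_id = "B-B-N"))

  tn <- make_semisynthetic_tn(spectra, compounds, seed = 5)
  expect_true(all(tn$decoy_compound != tn$true_compound))
  # isobaric candidates preferred: A's decoy is its 200 Da partner B
  expect_equal(tn$decoy_compound[1], "B-B-N")
  expect_identical(tn, make_semisynthetic_tn(spectra, compounds, seed = 5))

  two <- compounds[1:2, ]
  tn2 <- make_semisynthetic_tn(spectra, two, seed = 1)
  expect_equal(tn2$decoy_compound, c("B-B-N", "A-A-N"))  # forced swap

  one <- compounds[1, ]
  expect_error(make_semisynthetic_tn(spectra, one, seed = 1), "at least 2")
})

test_that("replication balances positives by an integer factor", {
  rows <- tibble::tibble(x = rnorm(55), label = rep(c(1, 0), c(5, 50)))
  out <- balance_by_replication(rows, factor = 10)
  expect_equal(sum(out$label == 1), 50)
  expect_equal(sum(out$label == 0), 50)
  expect_identical(balance_by_replication(rows, 1)[order(
    balance_by_replication(rows, 1)$x), ]$x, rows[order(rows$x), ]$x)
  for (f in c(2, 7)) {
    out_f <- balance_by_replication(rows, f)
    expect_equal(sum(out_f$label == 1), 5 * f)
    expect_equal(sum(out_f$label == 0), 50)
  }
})

test_that("correlated features are pruned to the importance-preferred set", {
  set.seed(2)
  n <- 200
  base <- rnorm(n)
  rows <- tibble::tibble(
    a = base,
    b = base + rnorm(n, 0, 0.01),       # near-duplicate of a
    c = rnorm(n),
    label = as.integer(base + rnorm(n, 0, 0.5) > 0)
  )
  kept <- prune_correlated(rows, r_threshold = 0.8)
  expect_equal(length(intersect(kept, c("a", "b"))), 1L)
  expect_true("c" %in% kept)

  ortho <- tibble::tibble(x = rnorm(n), y = rnorm(n), z = rnorm(n))
  expect_setequal(prune_correlated(ortho), c("x", "y", "z"))

  expect_warning(
    prune_correlated(tibble::tibble(k = rep(1, 10), x = rnorm(10))),
    "Constant")

  # property: surviving features never exceed the threshold pairwise
  for (rep in 1:5) {
    M <- matrix(rnorm(100 * 6), 100, 6)
    M[, 2] <- M[, 1] * 0.95 + rnorm(100, 0, 0.1)
    M[, 5] <- -M[, 4] + rnorm(100, 0, 0.05)
    tab <- tibble::as_tibble(as.data.frame(M))
    kept <- prune_correlated(tab, r_threshold = 0.8)
    C <- abs(stats::cor(tab[kept]))
    diag(C) <- 0
    expect_true(all(C <= 0.8))
  }
})

test_that("the KNN classifier separates labeled matches and reproduces", {
  set.seed(3)
  n <- 200
  rows <- tibble::tibble(
    f1 = c(rnorm(n, 0), rnorm(n, 6)),
    f2 = c(rnorm(n, 0), rnorm(n, -6)),
    label = rep(c(0L, 1L), each = n)
  )
  clf <- train_ptp(rows, "knn", seed = 1)
  p <- predict_ptp(clf, rows)
  expect_true(all(p >= 0 & p <= 1))
  cc <- confusion_counts(rows$label, as.integer(p >= 0.5))
  expect_gte(mcc(cc), 0.99)

  # flipped labels complement the probabilities within vote resolution
  flipped <- rows
  flipped$label <- 1L - flipped$label
  p_flip <- predict_ptp(train_ptp(flipped, "knn", seed = 1), rows)
  expect_true(all(abs((1 - p_flip) - p) <= 1 / 5 + 1e-12))

  clf2 <- train_ptp(rows, "knn", seed = 1)
  expect_identical(predict_ptp(clf2, rows), p)

  expect_error(train_ptp(rows[rows$label == 1, ], "knn"), "both labels")
  expect_error(predict_ptp(clf, rows[, "f1"]), "Missing feature")
})

test_that("single-neighbor lookups return exact memberships", {
  rows <- tibble::tibble(f1 = c(0, 10), f2 = c(0, 10), label = c(0L, 1L))
  clf <- train_ptp(rows, "knn", k = 1, seed = 1)
  expect_equal(predict_ptp(clf, rows[2, ]), 1.0)
  expect_equal(predict_ptp(clf, rows[1, ]), 0.0)
})

test_that("alternative classifier algorithms emit calibrated probabilities", {
  set.seed(4)
  n <- 150
  rows <- tibble::tibble(
    f1 = c(rnorm(n, 0), rnorm(n, 4)),
    f2 = rnorm(2 * n),
    label = rep(c(0L, 1L), each = n)
  )
  for (alg in c("logistic", "tree", "forest")) {
    clf <- train_ptp(rows, alg, seed = 2)
    p <- predict_ptp(clf, rows)
    expect_true(all(p >= 0 & p <= 1))
    cc <- confusion_counts(rows$label, as.integer(p >= 0.5))
    expect_gte(mcc(cc), 0.8)
  }
})

test_that("confusion metrics match their defining formulas", {
  expect_equal(mcc(list(tp = 10, tn = 10, fp = 0, fn = 0)), 1)
  expect_equal(mcc(list(tp = 0, tn = 0, fp = 10, fn = 10)), -1)
  expect_equal(mcc(list(tp = 5, tn = 5, fp = 5, fn = 5)), 0)
  expect_equal(mcc(list(tp = 0, tn = 10, fp = 0, fn = 0)), 0)  # degenerate

  expect_equal(recall_score(list(tp = 3, tn = 0, fp = 0, fn = 2)), 0.6)
  perfect <- list(tp = 7, tn = 13, fp = 0, fn = 0)
  expect_equal(weighted_f1(perfect), 1)
  expect_equal(fdr_score(list(tp = 8, tn = 0, fp = 2, fn = 0)), 0.2)
  expect_error(recall_score(list(tp = 0, tn = 5, fp = 1, fn = 0)), "undefined")

  truth <- c(1, 1, 0, 0, 1)
  pred <- c(1, 0, 0, 1, 1)
  cc <- confusion_counts(truth, pred)
  expect_equal(unlist(cc), c(tp = 2, tn = 1, fp = 1, fn = 1))
})

test_that("balanced-class FDR follows from the TP and FP rates", {
  expect_equal(fdr_from_rates(1, 0), 0)
  expect_equal(fdr_from_rates(0.5, 0.5), 0.5)
  # equal class sizes: identical counts computed either way
  counts <- list(tp = 988, fn = 12, fp = 234, tn = 766)
  expect_equal(fdr_score(counts), fdr_from_rates(0.988, 0.234))
})

test_that("FDR calibration equals a brute-force threshold sweep", {
  set.seed(5)
  n <- 300
  rows <- tibble::tibble(
    score = c(rnorm(n, 0, 1), rnorm(n, 1.5, 1)),  # overlapping classes
    label = rep(c(0L, 1L), each = n)
  )
  clf <- train_ptp(rows, "knn", seed = 1)
  cal <- calibrate_fdr(clf, rows, fdr_targets = c(0.05, 0.2))
  ptp <- predict_ptp(clf, rows)
  for (i in seq_len(nrow(cal))) {
    t <- cal$threshold[i]
    fp <- sum(ptp >= t & rows$label == 0)
    tp <- sum(ptp >= t & rows$label == 1)
    want <- if (tp + fp == 0) NA_real_ else fp / (tp + fp)
    expect_equal(cal$fdr[i], want)
  }
  known <- !is.na(cal$fdr_adjusted)
  expect_true(all(diff(cal$fdr_adjusted[known]) <= 1e-12))
  targets <- attr(cal, "targets")
  expect_equal(nrow(targets), 2L)
  # the reported threshold is minimal for its bound
  for (j in seq_len(nrow(targets))) {
    if (!targets$attainable[j]) next
    t <- targets$threshold[j]
    expect_lte(cal$fdr_adjusted[match(t, cal$threshold)], targets$fdr_target[j])
    below <- known & cal$threshold < t
    if (any(below)) {
      expect_true(all(cal$fdr_adjusted[below] > targets$fdr_target[j]))
    }
  }
})

test_that("cleanly separated scores give zero FDR above the gap", {
  rows <- tibble::tibble(f1 = c(rnorm(50, -5), rnorm(50, 5)),
                         label = rep(c(0L, 1L), each = 50))
  clf <- train_ptp(rows, "knn", seed = 1)
  cal <- calibrate_fdr(clf, rows, fdr_targets = 0.05)
  expect_true(attr(cal, "targets")$attainable)
  expect_equal(min(cal$fdr_adjusted, na.rm = TRUE), 0)

  all_tn <- tibble::tibble(f1 = rnorm(40), label = 0L)
  expect_warning(cal_tn <- calibrate_fdr(clf, all_tn), "single class")
  expect_true(all(cal_tn$fdr[cal_tn$n_accepted > 0] == 1))
})
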