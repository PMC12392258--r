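#' Retention-index error of a spectral match
#'
#' The signed difference between the structure-derived and the
#' spectrum-derived retention-time index, `RTI_MF - RTI_CNL`. For a true
#' positive match the two estimates describe the same molecule and the
#' error is small; for a match to the wrong candidate structure the
#' structure-derived value belongs to another molecule and the error
#' inflates.
#'
#' @param rti_mf fingerprint-model RTI prediction(s) for the candidate
#'   structure.
#' @param rti_cnl CNL-model RTI prediction(s) for the query spectrum.
#' @return `rti_mf - rti_cnl`, vectorized.
#' @export
rti_error <- function(rti_mf, rti_cnl) {
  stopifnot(is.numeric(rti_mf), is.numeric(rti_cnl))
  rti_mf - rti_cnl
}

#' Pair spectra with wrong candidate structures (semisynthetic negatives)
#'
#' Builds labeled true-negative material: every spectrum is paired with a
#' candidate compound different from its true compound, sampled uniformly
#' with a fixed seed. Candidates are drawn from compounds whose
#' monoisotopic mass lies within `mass_tol` of the true compound's mass
#' (the accurate-mass retrieval window that produces real wrong-candidate
#' hits); when no isobaric candidate exists, any wrong compound is used.
#'
#' @param spectra an `nta_spectra` tibble whose `compound_id` gives the
#'   true identity.
#' @param compounds tibble with `inchikey` and `monoisotopic_mass`.
#' @param seed integer seed.
#' @param mass_tol candidate mass window (Da, default 0.01).
#' @return A tibble with `spectrum_id`, `true_compound`, `decoy_compound`.
#' @export
make_semisynthetic_tn <- function(spectra, compounds, seed = 1L,
                                  mass_tol = 0.01) {
  stopifnot(is.data.frame(spectra), is.data.frame(compounds))
  if (dplyr::n_distinct(compounds$inchikey) < 2L) {
    stop("Need at least 2 distinct compounds to build decoy pairings.",
         call. = FALSE)
  }
  old <- get0(".Random.seed", globalenv())
  on.exit(restore_rng(old))
  set.seed(seed)
  mass_of <- stats::setNames(compounds$monoisotopic_mass, compounds$inchikey)
  decoy <- vapply(seq_len(nrow(spectra)), function(i) {
    truth <- spectra$compound_id[i]
    pool <- compounds$inchikey[compounds$inchikey != truth]
    if (!is.na(truth) && truth %in% names(mass_of)) {
      iso <- pool[abs(mass_of[pool] - mass_of[[truth]]) <= mass_tol]
      if (length(iso)) pool <- iso
    }
    pool[sample.int(length(pool), 1L)]
  }, character(1))
  tibble::tibble(spectrum_id = spectra$spectrum_id,
                 true_compound = spectra$compound_id,
                 decoy_compound = decoy)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Balance a labeled match table by replicating positives
#'
#' True-positive matches are heavily outnumbered by negatives; the
#' training table is balanced by including `factor - 1` additional
#' replicates of every label-1 row (default factor 10). Label-0 rows are
#' unchanged.
#'
#' @param rows tibble with a 0/1 `label` column.
#' @param factor total number of copies of each positive row (>= 1).
#' @return The replicated tibble with a `replicate_id` column.
#' @export
balance_by_replication <- function(rows, factor = 10L) {
  stopifnot(is.data.frame(rows), "label" %in% names(rows), factor >= 1L)
  pos <- rows[rows$label == 1, ]
  neg <- rows[rows$label == 0, ]
  neg$replicate_id <- 1L
  reps <- purrr::map_dfr(seq_len(factor), function(r) {
    pos$replicate_id <- as.integer(r)
    pos
  })
  dplyr::bind_rows(neg, reps)
}

#' Drop redundant, correlated features
#'
#' Iteratively removes features until no pair has Pearson |r| above the
#' threshold; within an offending pair the feature of lower importance is
#' dropped. Constant features yield an undefined correlation, treated as
#' 0 with a warning.
#'
#' @param rows tibble of numeric feature columns (a `label` column, if
#'   present, is excluded from pruning and used for default importance).
#' @param r_threshold Pearson threshold (default 0.80).
#' @param importance named numeric vector ranking the features (higher =
#'   keep); defaults to the absolute correlation of each feature with
#'   `label`, or the feature variance when no label exists.
#' @return Character vector of retained feature names.
#' @export
prune_correlated <- function(rows, r_threshold = 0.80, importance = NULL) {
  stopifnot(is.data.frame(rows), nrow(rows) >= 2L)
  feats <- setdiff(names(rows)[vapply(rows, is.numeric, logical(1))],
                   c("label", "weight", "replicate_id"))
  X <- as.matrix(rows[feats])
  const <- apply(X, 2, stats::sd) == 0
  if (any(const)) {
    warning("Constant feature(s) ", paste(feats[const], collapse = ", "),
            ": correlation undefined, treated as 0.", call. = FALSE)
  }
  if (is.null(importance)) {
    importance <- if ("label" %in% names(rows)) {
      vapply(feats, function(f) {
        r <- suppressWarnings(stats::cor(rows[[f]], rows$label))
        if (is.na(r)) 0 else abs(r)
      }, numeric(1))
    } else {
      apply(X, 2, stats::var)
    }
  }
  stopifnot(all(feats %in% names(importance)))
  keep <- feats
  repeat {
    C <- suppressWarnings(abs(stats::cor(X[, keep, drop = FALSE])))
    C[is.na(C)] <- 0
    diag(C) <- 0
    if (all(C <= r_threshold)) break
    worst <- which(C == max(C), arr.ind = TRUE)[1, ]
    pair <- keep[worst]
    drop <- pair[which.min(importance[pair])]
    keep <- setdiff(keep, drop)
    if (length(keep) == 1L) break
  }
  keep
}

# ---- confusion-matrix metrics ----------------------------------------------

#' Confusion counts and derived classification metrics
#'
#' `confusion_counts()` tabulates 0/1 truth against 0/1 predictions.
#' `mcc()` is the Matthews correlation coefficient
#' (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)), defined as 0
#' when the denominator vanishes. `recall_score()` is TP / (TP + FN).
#' `f1_score()` is the per-class F1, TP / (TP + (FP + FN)/2);
#' `weighted_f1()` averages the class-1 and class-0 F1 weighted by class
#' support. `fdr_score()` is the false discovery rate FP / (TP + FP).
#'
#' @param truth,predicted 0/1 vectors of equal length.
#' @return `confusion_counts()` returns a one-row tibble with `tp`,
#'   `tn`, `fp`, `fn`; the metric functions return a single number.
#' @export
confusion_counts <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted),
            all(truth %in% c(0, 1)), all(predicted %in% c(0, 1)))
  tibble::tibble(
    tp = sum(truth == 1 & predicted == 1),
    tn = sum(truth == 0 & predicted == 0),
    fp = sum(truth == 0 & predicted == 1),
    fn = sum(truth == 1 & predicted == 0)
  )
}

#' @rdname confusion_counts
#' @param counts a one-row tibble/list with `tp`, `tn`, `fp`, `fn`.
#' @export
mcc <- function(counts) {
  tp <- as.numeric(counts$tp); tn <- as.numeric(counts$tn)
  fp <- as.numeric(counts$fp); fn <- as.numeric(counts$fn)
  denom <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / denom
}

#' @rdname confusion_counts
#' @export
recall_score <- function(counts) {
  with(counts, {
    if (tp + fn == 0) stop("Recall undefined: no positive support.",
                           call. = FALSE)
    tp / (tp + fn)
  })
}

#' @rdname confusion_counts
#' @param positive which label the F1 is computed for (1 or 0).
#' @export
f1_score <- function(counts, positive = 1) {
  with(counts, {
    if (positive == 1) {
      if (tp + fn == 0) stop("F1 undefined: no class-1 support.", call. = FALSE)
      tp / (tp + 0.5 * (fp + fn))
    } else {
      if (tn + fp == 0) stop("F1 undefined: no class-0 support.", call. = FALSE)
      tn / (tn + 0.5 * (fn + fp))
    }
  })
}

#' @rdname confusion_counts
#' @export
weighted_f1 <- function(counts) {
  with(counts, {
    n1 <- tp + fn
    n0 <- tn + fp
    if (n1 == 0 || n0 == 0) stop("Weighted F1 needs both class supports > 0.",
                                 call. = FALSE)
    (n1 * f1_score(counts, 1) + n0 * f1_score(counts, 0)) / (n1 + n0)
  })
}

#' @rdname confusion_counts
#' @export
fdr_score <- function(counts) {
  with(counts, {
    if (tp + fp == 0) return(NA_real_)
    fp / (tp + fp)
  })
}

#' FDR implied by TP and FP rates under balanced classes
#'
#' With equally sized positive and negative populations the false
#' discovery rate reduces to FPR / (TPR + FPR).
#'
#' @param tpr,fpr true/false positive rates in \[0, 1\].
#' @return FDR in \[0, 1\].
#' @export
fdr_from_rates <- function(tpr, fpr) {
  stopifnot(tpr >= 0, tpr <= 1, fpr >= 0, fpr <= 1)
  if (tpr + fpr == 0) return(NA_real_)
  fpr / (tpr + fpr)
}

# ---- the P(TP) classifier ---------------------------------------------------

#' Train the true-positive-probability classifier
#'
#' Fits a binary classifier returning the class probability P(TP) that an
#' individual spectral match is a true positive. The default algorithm is
#' k-nearest neighbors (k = 5) on features standardized to zero mean and
#' unit SD using training statistics; the probability is the neighbor
#' vote fraction. Logistic regression, a decision tree and a random
#' forest are available for comparison.
#'
#' @param rows tibble with numeric feature columns and a 0/1 `label`
#'   column (both labels must be present). Columns `weight` and
#'   `replicate_id` are ignored as features.
#' @param algorithm `"knn"`, `"logistic"`, `"tree"` or `"forest"`.
#' @param features optional character vector restricting the feature set
#'   (e.g. the output of [prune_correlated()]).
#' @param k neighbor count for KNN (default 5).
#' @param seed integer seed (forest bootstraps; KNN distance-tie breaks).
#' @return An object of class `ptp_model`.
#' @export
train_ptp <- function(rows, algorithm = c("knn", "logistic", "tree", "forest"),
                      features = NULL, k = 5L, seed = 1L) {
  algorithm <- match.arg(algorithm)
  stopifnot(is.data.frame(rows), "label" %in% names(rows))
  if (dplyr::n_distinct(rows$label) < 2L) {
    stop("Training data must contain both labels.", call. = FALSE)
  }
  if (is.null(features)) {
    features <- setdiff(names(rows)[vapply(rows, is.numeric, logical(1))],
                        c("label", "weight", "replicate_id"))
  }
  stopifnot(length(features) >= 1L, all(features %in% names(rows)))
  X <- as.matrix(rows[features])
  if (any(!is.finite(X))) stop("All features must be finite.", call. = FALSE)
  center <- colMeans(X)
  scale_ <- apply(X, 2, stats::sd)
  scale_[scale_ == 0] <- 1
  Z <- scale(X, center = center, scale = scale_)
  y <- as.integer(rows$label)
  fit <- switch(algorithm,
    knn = list(train = Z, y = y),
    logistic = {
      df <- data.frame(Z, label = y)
      stats::glm(label ~ ., data = df, family = stats::binomial())
    },
    tree = {
      df <- data.frame(Z, label = factor(y, levels = c(0, 1)))
      rpart::rpart(label ~ ., data = df, method = "class")
    },
    forest = ranger::ranger(x = Z, y = factor(y, levels = c(0, 1)),
                            probability = TRUE, num.trees = 500L,
                            seed = seed, num.threads = 1L)
  )
  structure(list(algorithm = algorithm, fit = fit, features = features,
                 center = center, scale = scale_, k = as.integer(k),
                 seed = as.integer(seed),
                 n = nrow(rows), n_pos = sum(y == 1), n_neg = sum(y == 0)),
            class = "ptp_model")
}

#' @export
print.ptp_model <- function(x, ...) {
  cat("<ptp_model> ", x$algorithm,
      if (x$algorithm == "knn") paste0(" (k = ", x$k, ")"),
      " | features: ", paste(x$features, collapse = ", "),
      " | n = ", x$n, " (", x$n_pos, " TP / ", x$n_neg, " TN)\n", sep = "")
  invisible(x)
}

#' Predict P(TP) for spectral-match feature rows
#'
#' Features are standardized with the model's training statistics before
#' prediction; P(0) is exactly `1 - P(TP)` for every match.
#'
#' @param model a [train_ptp()] fit.
#' @param rows tibble containing the model's feature columns.
#' @return Numeric vector of P(TP) in \[0, 1\].
#' @export
predict_ptp <- function(model, rows) {
  stopifnot(inherits(model, "ptp_model"))
  missing <- setdiff(model$features, names(rows))
  if (length(missing)) {
    stop("Missing feature column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  Z <- scale(as.matrix(rows[model$features]),
             center = model$center, scale = model$scale)
  p1 <- switch(model$algorithm,
    knn = {
      old <- get0(".Random.seed", globalenv())
      on.exit(restore_rng(old))
      set.seed(model$seed)
      pred <- class::knn(train = model$fit$train, test = Z,
                         cl = factor(model$fit$y, levels = c(0, 1)),
                         k = min(model$k, nrow(model$fit$train)),
                         prob = TRUE, use.all = TRUE)
      vote <- attr(pred, "prob")
      ifelse(pred == "1", vote, 1 - vote)
    },
    logistic = as.numeric(stats::predict(model$fit,
                                         newdata = data.frame(Z),
                                         type = "response")),
    tree = as.numeric(stats::predict(model$fit, newdata = data.frame(Z),
                                     type = "prob")[, "1"]),
    forest = as.numeric(stats::predict(model$fit, data = Z,
                                       num.threads = 1L)$predictions[, "1"])
  )
  pmin(pmax(p1, 0), 1)
}

#' Tidy the P(TP) classifier
#'
#' @param x a `ptp_model`.
#' @param ... unused.
#' @return A tibble of the retained features with their training
#'   standardization statistics.
#' @exportS3Method generics::tidy
tidy.ptp_model <- function(x, ...) {
  tibble::tibble(feature = x$features,
                 center = unname(x$center),
                 scale = unname(x$scale))
}

#' @rdname tidy.ptp_model
#' @exportS3Method generics::glance
glance.ptp_model <- function(x, ...) {
  tibble::tibble(algorithm = x$algorithm, k = x$k, n = x$n,
                 n_pos = x$n_pos, n_neg = x$n_neg,
                 n_features = length(x$features), seed = x$seed)
}

# ---- FDR calibration --------------------------------------------------------

#' Calibrate P(TP) thresholds against the false discovery rate
#'
#' Sweeps a threshold grid over P(TP) values on a labeled evaluation set:
#' at each threshold, matches with P(TP) at or above it are accepted and
#' FDR = FP / (TP + FP) is computed. The curve is made monotone
#' (non-increasing FDR as the threshold rises) by isotonic
#' post-processing (running minimum over ascending thresholds), and the
#' minimal threshold reaching each requested FDR bound is reported; an
#' unattainable bound yields `NA`.
#'
#' @param model a [train_ptp()] fit.
#' @param rows labeled evaluation tibble (both classes present).
#' @param fdr_targets FDR bounds to solve for (default 5% and 10%).
#' @return A tibble of class `ptp_calibration` with columns `threshold`,
#'   `n_accepted`, `fdr`, `fdr_adjusted`; the per-target solutions are in
#'   `attr(, "targets")`.
#' @export
calibrate_fdr <- function(model, rows, fdr_targets = c(0.05, 0.10)) {
  stopifnot("label" %in% names(rows))
  if (dplyr::n_distinct(rows$label) < 2L) {
    warning("Calibration set contains a single class; the FDR curve is ",
            "degenerate (0 or 1 wherever matches are accepted).",
            call. = FALSE)
  }
  ptp <- predict_ptp(model, rows)
  grid <- sort(unique(c(0, ptp, 1)))
  curve <- purrr::map_dfr(grid, function(t) {
    acc <- ptp >= t
    tp <- sum(acc & rows$label == 1)
    fp <- sum(acc & rows$label == 0)
    tibble::tibble(threshold = t, n_accepted = tp + fp,
                   fdr = if (tp + fp == 0) NA_real_ else fp / (tp + fp))
  })
  known <- !is.na(curve$fdr)
  curve$fdr_adjusted <- curve$fdr
  curve$fdr_adjusted[known] <- cummin(curve$fdr[known])
  targets <- purrr::map_dfr(fdr_targets, function(b) {
    ok <- which(known & curve$fdr_adjusted <= b)
    tibble::tibble(fdr_target = b,
                   threshold = if (length(ok)) curve$threshold[min(ok)] else NA_real_,
                   attainable = length(ok) > 0)
  })
  attr(curve, "targets") <- targets
  class(curve) <- c("ptp_calibration", class(curve))
  curve
}

#' Plot an FDR calibration curve
#'
#' @param object a [calibrate_fdr()] result.
#' @param ... unused.
#' @return A ggplot of adjusted FDR against the P(TP) threshold, with the
#'   requested FDR bounds as horizontal lines.
#' @exportS3Method ggplot2::autoplot
autoplot.ptp_calibration <- function(object, ...) {
  targets <- attr(object, "targets")
  df <- object[!is.na(object$fdr_adjusted), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold, y = .data$fdr_adjusted)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = targets$fdr_target, linetype = "dotted") +
    ggplot2::labs(x = "P(TP) threshold", y = "FDR (isotonic)",
                  title = "FDR-calibrated P(TP) cut-offs") +
    ggplot2::theme_minimal()
}
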