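#' Fingerprint-stratified train/test split
#'
#' Splits compound records for retention-model training so that the split
#' is stratified by *structure* rather than by retention: fingerprint
#' count vectors are clustered with k-means (k = ceiling(sqrt(n)), on the
#' raw counts) and each cluster is split at the requested fraction. Two
#' records with identical fingerprints always land in the same stratum.
#'
#' @param compounds tibble with a matrix column `fp` (see
#'   [fingerprint_compounds()]).
#' @param fraction training fraction in (0, 1).
#' @param seed integer seed controlling both clustering and within-stratum
#'   sampling.
#' @return A list with tibbles `train` and `test`; their union is the
#'   input partition.
#' @export
split_by_fingerprint_strata <- function(compounds, fraction = 0.8, seed = 1L) {
  stopifnot(is.data.frame(compounds), "fp" %in% names(compounds))
  n <- nrow(compounds)
  if (n < 2L) stop("Need at least 2 records to split.", call. = FALSE)
  if (fraction <= 0 || fraction >= 1) stop("`fraction` must be in (0, 1).",
                                           call. = FALSE)
  fp <- compounds$fp
  distinct <- unique(fp)
  k <- min(ceiling(sqrt(n)), nrow(distinct))
  cluster <- if (k == 1L) {
    rep(1L, n)
  } else {
    set.seed(seed)
    km <- suppressWarnings(stats::kmeans(fp, centers = distinct[
      seq(1, nrow(distinct), length.out = k), , drop = FALSE], iter.max = 50))
    km$cluster
  }
  set.seed(seed + 1L)
  in_train <- logical(n)
  for (cl in unique(cluster)) {
    idx <- which(cluster == cl)
    n_tr <- round(fraction * length(idx))
    if (length(idx) == 1L) {
      # singleton strata go to train unless that would empty the test side
      n_tr <- 1L
    }
    in_train[sample(idx, n_tr)] <- TRUE
  }
  # guarantee a non-degenerate partition
  if (all(in_train)) in_train[sample.int(n, 1)] <- FALSE
  if (!any(in_train)) in_train[sample.int(n, 1)] <- TRUE
  list(train = compounds[in_train, ], test = compounds[!in_train, ])
}

#' Leverage-ranked train/test split
#'
#' Deterministic split used for the CNL retention model: rows are ranked
#' by their leverage in the design matrix and test rows are taken by
#' systematic sampling over the ranked list, so both sides span the full
#' leverage range (no randomness is involved).
#'
#' @param X numeric design matrix.
#' @param fraction training fraction in (0, 1).
#' @return A list with integer vectors `train_idx` and `test_idx`.
#' @export
split_by_leverage <- function(X, fraction = 0.7) {
  X <- as.matrix(X)
  if (fraction <= 0 || fraction >= 1) stop("`fraction` must be in (0, 1).",
                                           call. = FALSE)
  n <- nrow(X)
  if (n < 2L) stop("Need at least 2 rows to split.", call. = FALSE)
  ad <- suppressWarnings(fit_ad(X))
  if (n <= ncol(X)) {
    warning("n <= p: leverage split computed through a pseudo-inverse.",
            call. = FALSE)
  }
  ranked <- order(ad$training_leverage, seq_len(n))  # stable
  n_test <- max(1L, round((1 - fraction) * n))
  step <- n / n_test
  pos <- pmin(n, pmax(1L, ceiling(step * seq_len(n_test) - step / 2)))
  pos <- unique(pos)
  test_idx <- sort(ranked[pos])
  list(train_idx = setdiff(seq_len(n), test_idx), test_idx = test_idx)
}

#' Train a retention-time-index regressor
#'
#' Fits a random-forest regression from molecular-fingerprint or CNL
#' features to harmonized retention-time indices (RTI), together with the
#' leverage applicability domain of the training design matrix. Defaults:
#' 500 fully grown trees (`min.node.size = 1`), regression-standard
#' `mtry = max(floor(p/3), 1)`, single-threaded and seed-controlled so
#' refits reproduce identical predictions.
#'
#' @param x numeric feature matrix (n x p), n >= 10.
#' @param y numeric RTI targets.
#' @param feature_space `"fingerprint"` (Model-1-style) or `"cnl"`
#'   (Model-2-style); metadata only.
#' @param seed integer seed for the forest.
#' @param num_trees,mtry,min_node_size forest hyperparameters.
#' @return An object of class `rti_model`.
#' @export
train_rti <- function(x, y, feature_space = c("fingerprint", "cnl"),
                      seed = 1L, num_trees = 500L, mtry = NULL,
                      min_node_size = 1L) {
  feature_space <- match.arg(feature_space)
  x <- as.matrix(x)
  if (nrow(x) != length(y)) stop("rows(x) must equal length(y).", call. = FALSE)
  if (nrow(x) < 10L) stop("Need at least 10 training rows.", call. = FALSE)
  if (any(!is.finite(y))) stop("RTI targets must be finite.", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  if (is.null(mtry)) mtry <- max(floor(ncol(x) / 3), 1L)
  forest <- ranger::ranger(
    x = x, y = y, num.trees = num_trees, mtry = mtry,
    min.node.size = min_node_size, seed = seed, num.threads = 1L,
    importance = "impurity", respect.unordered.factors = FALSE
  )
  ad <- suppressWarnings(fit_ad(x))
  structure(list(forest = forest, ad = ad, feature_space = feature_space,
                 feature_names = colnames(x),
                 meta = list(n = nrow(x), p = ncol(x), seed = seed,
                             num_trees = num_trees, mtry = mtry,
                             min_node_size = min_node_size)),
            class = "rti_model")
}

#' @export
print.rti_model <- function(x, ...) {
  cat("<rti_model> ", x$feature_space, " -> RTI | n = ", x$meta$n,
      ", p = ", x$meta$p, ", trees = ", x$meta$num_trees,
      " | AD threshold = ", signif(x$ad$threshold, 4), "\n", sep = "")
  invisible(x)
}

#' Predict retention-time indices with applicability-domain flags
#'
#' @param model an [train_rti()] fit.
#' @param x feature matrix (or single vector) with the model's p columns.
#' @return A tibble with columns `rti`, `leverage`, `in_domain`.
#' @export
predict_rti <- function(model, x) {
  stopifnot(inherits(model, "rti_model"))
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(x) != model$meta$p) {
    stop("Query has ", ncol(x), " features; model expects ", model$meta$p, ".",
         call. = FALSE)
  }
  colnames(x) <- model$feature_names
  pred <- stats::predict(model$forest, data = x, num.threads = 1L)$predictions
  h <- leverage(model$ad, x)
  tibble::tibble(rti = as.numeric(pred), leverage = h,
                 in_domain = h <= model$ad$threshold)
}

#' Regression performance metrics
#'
#' RMSE = sqrt(mean((y - yhat)^2)), MAE = mean |y - yhat|, MRE =
#' mean(|y - yhat| / |y|) * 100 (%), R^2 = 1 - SSres/SStot.
#'
#' @param y observed values.
#' @param yhat predicted values (same length).
#' @param mre compute the mean relative error (requires all `y != 0`).
#' @return A one-row tibble with `rmse`, `mae`, `mre`, `r2`, `n`.
#' @export
evaluate_regression <- function(y, yhat, mre = TRUE) {
  if (length(y) != length(yhat)) stop("y and yhat differ in length.",
                                      call. = FALSE)
  if (length(y) < 1L) stop("Need at least one observation.", call. = FALSE)
  err <- y - yhat
  if (mre && any(y == 0)) {
    stop("MRE is undefined when some y equal 0; call with mre = FALSE.",
         call. = FALSE)
  }
  sstot <- sum((y - mean(y))^2)
  ssres <- sum(err^2)
  r2 <- if (sstot == 0) {
    if (ssres == 0) 1 else NA_real_
  } else {
    1 - ssres / sstot
  }
  tibble::tibble(
    rmse = sqrt(mean(err^2)),
    mae = mean(abs(err)),
    mre = if (mre) mean(abs(err) / abs(y)) * 100 else NA_real_,
    r2 = r2,
    n = length(y)
  )
}

# ---- broom-style accessors --------------------------------------------------

#' Tidy a retention-model fit
#'
#' @param x an `rti_model`.
#' @param ... unused.
#' @return A tibble of per-feature impurity importance, descending.
#' @exportS3Method generics::tidy
tidy.rti_model <- function(x, ...) {
  imp <- x$forest$variable.importance
  dplyr::arrange(tibble::tibble(feature = names(imp), importance = unname(imp)),
                 dplyr::desc(.data$importance))
}

#' @rdname tidy.rti_model
#' @return `glance()` returns a one-row tibble of fit metadata (n, p,
#'   out-of-bag R^2, AD threshold, hyperparameters).
#' @exportS3Method generics::glance
glance.rti_model <- function(x, ...) {
  tibble::tibble(
    feature_space = x$feature_space,
    n = x$meta$n, p = x$meta$p,
    num_trees = x$meta$num_trees, mtry = x$meta$mtry,
    seed = x$meta$seed,
    oob_r2 = x$forest$r.squared,
    ad_threshold = x$ad$threshold
  )
}

#' Predicted-versus-observed plot for a retention model
#'
#' @param object an `rti_model`.
#' @param x feature matrix of evaluation rows.
#' @param y observed RTI values for those rows.
#' @param ... unused.
#' @return A ggplot: predictions against observations with the identity
#'   line, out-of-domain points marked.
#' @exportS3Method ggplot2::autoplot
autoplot.rti_model <- function(object, x, y, ...) {
  pred <- predict_rti(object, x)
  pred$observed <- y
  ggplot2::ggplot(pred, ggplot2::aes(x = .data$observed, y = .data$rti,
                                     colour = .data$in_domain)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "observed RTI", y = "predicted RTI",
                  colour = "in domain",
                  title = paste0(object$feature_space, " → RTI")) +
    ggplot2::theme_minimal()
}
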