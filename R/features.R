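PROTON_MASS <- 1.00728  # Da, mass of H+ used for [M+H]+ bookkeeping

#' Neutral losses of a spectrum
#'
#' The cumulative neutral loss (CNL) representation of an MS/MS spectrum:
#' for every fragment peak, loss = precursor m/z - fragment m/z. Negative
#' losses (fragments above the precursor, already guarded during peak
#' cleaning) are excluded; a fragment equal to the precursor yields loss 0.
#'
#' @param spectra an `nta_spectra` tibble.
#' @return A tibble with `spectrum_id` and ascending `loss` (Da), one row
#'   per fragment.
#' @export
neutral_losses <- function(spectra) {
  stopifnot(is.data.frame(spectra), all(c("precursor_mz", "peaks") %in% names(spectra)))
  if (any(!is.finite(spectra$precursor_mz))) {
    stop("Every spectrum needs a finite precursor m/z to compute neutral losses.",
         call. = FALSE)
  }
  purrr::map2_dfr(spectra$spectrum_id, seq_len(nrow(spectra)), function(id, i) {
    loss <- spectra$precursor_mz[i] - spectra$peaks[[i]]$mz
    keep <- loss >= 0
    tibble::tibble(spectrum_id = id,
                   loss = sort(loss[keep]),
                   intensity = spectra$peaks[[i]]$intensity[keep][order(loss[keep])])
  })
}

#' Masses-of-interest (MOI) list
#'
#' A strictly ascending set of neutral-loss masses with a matching
#' tolerance. Adjacent masses must differ by more than twice the tolerance
#' so the CNL indicator bins never overlap.
#'
#' @param masses numeric vector of neutral-loss masses (Da).
#' @param tolerance half-width of each bin (Da, > 0). Default 0.01 Da.
#' @return An object of class `moi_list`.
#' @export
moi_list <- function(masses, tolerance = 0.01) {
  masses <- sort(as.numeric(masses))
  stopifnot(is.numeric(tolerance), tolerance > 0)
  if (anyDuplicated(masses) || (length(masses) > 1 &&
                                any(diff(masses) <= 2 * tolerance))) {
    stop("MOI masses must be strictly ascending with gaps > 2*tolerance ",
         "so bins do not overlap.", call. = FALSE)
  }
  structure(list(masses = masses, tolerance = tolerance), class = "moi_list")
}

#' @export
print.moi_list <- function(x, ...) {
  cat("<moi_list> ", length(x$masses), " masses, tolerance ±",
      x$tolerance, " Da\n", sep = "")
  invisible(x)
}

#' Read / write an MOI list CSV
#'
#' The on-disk format is a CSV with a single `mass_da` column.
#'
#' @param path CSV path.
#' @param tolerance bin half-width passed to [moi_list()].
#' @return [read_moi_list()] returns a `moi_list`; [write_moi_list()]
#'   returns `path` invisibly.
#' @export
read_moi_list <- function(path, tolerance = 0.01) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"mass_da" %in% names(tab)) {
    stop("MOI list CSV must have a 'mass_da' column.", call. = FALSE)
  }
  moi_list(tab$mass_da, tolerance = tolerance)
}

#' @rdname read_moi_list
#' @param moi a `moi_list`.
#' @export
write_moi_list <- function(moi, path) {
  readr::write_csv(tibble::tibble(mass_da = moi$masses), path)
  invisible(path)
}

#' CNL indicator features over an MOI list
#'
#' Converts each spectrum into the Model-2 feature vector: a binary
#' indicator per MOI bin (1 iff some neutral loss of the spectrum lies
#' within ±tolerance of the MOI mass) plus the monoisotopic mass as an
#' additional feature. When the spectrum carries no monoisotopic mass the
#' positive-mode fallback precursor - 1.00728 Da is used. Indicators
#' depend on fragment m/z only, so the featurization is invariant to
#' intensity rescaling.
#'
#' Spectra setting fewer than `min_moi` indicators carry too little CNL
#' signal for retention modeling and are dropped with a warning (the
#' at-least-2-MOIs rule) unless `drop_below_min = FALSE`.
#'
#' @param spectra an `nta_spectra` tibble.
#' @param moi a [moi_list()].
#' @param min_moi minimum number of set indicators (default 2).
#' @param drop_below_min drop spectra failing the rule (default `TRUE`).
#' @return A tibble with `spectrum_id`, `monoisotopic_mass`, `n_moi`, and
#'   a matrix column `cnl` of 0/1 indicators (one column per MOI mass).
#' @export
cnl_features <- function(spectra, moi, min_moi = 2L, drop_below_min = TRUE) {
  stopifnot(inherits(moi, "moi_list"))
  ind <- matrix(0L, nrow = nrow(spectra), ncol = length(moi$masses),
                dimnames = list(NULL, paste0("moi_", seq_along(moi$masses))))
  for (i in seq_len(nrow(spectra))) {
    loss <- spectra$precursor_mz[i] - spectra$peaks[[i]]$mz
    loss <- loss[loss >= 0]
    ind[i, ] <- as.integer(bin_hits(loss, moi$masses, moi$tolerance))
  }
  mono <- spectra$monoisotopic_mass
  fallback <- is.na(mono)
  mono[fallback] <- spectra$precursor_mz[fallback] - PROTON_MASS
  out <- tibble::tibble(spectrum_id = spectra$spectrum_id,
                        monoisotopic_mass = mono,
                        n_moi = as.integer(rowSums(ind)))
  out$cnl <- ind
  if (drop_below_min && any(out$n_moi < min_moi)) {
    warning(sum(out$n_moi < min_moi), " spectrum/spectra below the ",
            min_moi, "-MOI minimum were dropped.", call. = FALSE)
    out <- out[out$n_moi >= min_moi, ]
  }
  out
}

# for each moi mass, is any loss within ±tol?  vectorized interval test
bin_hits <- function(losses, masses, tol) {
  if (length(losses) == 0L) return(rep(FALSE, length(masses)))
  losses <- sort(losses)
  lo <- findInterval(masses - tol, losses)
  hi <- findInterval(masses + tol, losses)
  hi > lo | (lo >= 1 & abs(losses[pmax(lo, 1)] - masses) <= tol)
}

#' Design matrix for CNL regression
#'
#' Binds the CNL indicator matrix with the monoisotopic-mass column into
#' the numeric design matrix consumed by [train_rti()] and [fit_ad()].
#'
#' @param features output of [cnl_features()].
#' @return A numeric matrix with `length(moi) + 1` columns.
#' @export
cnl_design_matrix <- function(features) {
  stopifnot(is.data.frame(features), "cnl" %in% names(features))
  cbind(features$cnl, monoisotopic_mass = features$monoisotopic_mass)
}

#' Select masses-of-interest from a spectrum corpus
#'
#' Screens the neutral losses of a corpus for high-probability loss bins:
#' losses are grouped into non-overlapping bins at the stated tolerance
#' (1-D single-linkage with gap > tolerance, centroid = intensity-weighted
#' mean), and bins whose document frequency (fraction of spectra
#' containing the loss) reaches `min_frequency` are retained. Overlapping
#' retained bins are merged until the [moi_list()] spacing invariant
#' holds.
#'
#' @param spectra an `nta_spectra` tibble (non-empty).
#' @param min_frequency minimum fraction of spectra containing the bin.
#' @param tolerance bin half-width (Da).
#' @return A [moi_list()].
#' @export
select_mois <- function(spectra, min_frequency = 0.05, tolerance = 0.01) {
  if (!is.data.frame(spectra) || nrow(spectra) == 0L) {
    stop("Cannot select MOIs from an empty corpus.", call. = FALSE)
  }
  nl <- neutral_losses(spectra)
  if (nrow(nl) == 0L) stop("Corpus contains no neutral losses.", call. = FALSE)
  nl <- nl[order(nl$loss), ]
  bin_id <- cumsum(c(1, diff(nl$loss) > tolerance))
  bins <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(bin = bin_id, loss = nl$loss,
                                   w = pmax(nl$intensity, 1e-12),
                                   spectrum_id = nl$spectrum_id),
                    .data$bin),
    centroid = sum(.data$loss * .data$w) / sum(.data$w),
    doc_freq = dplyr::n_distinct(.data$spectrum_id) / nrow(spectra),
    weight = sum(.data$w),
    .groups = "drop"
  )
  keep <- bins[bins$doc_freq >= min_frequency, ]
  if (nrow(keep) == 0L) {
    stop("No loss bin reaches min_frequency = ", min_frequency, call. = FALSE)
  }
  centroids <- keep$centroid
  weights <- keep$weight
  # merge any retained bins closer than the non-overlap spacing
  repeat {
    gaps <- diff(centroids)
    bad <- which(gaps <= 2 * tolerance)
    if (length(bad) == 0L) break
    i <- bad[1]
    merged <- stats::weighted.mean(centroids[c(i, i + 1)], weights[c(i, i + 1)])
    centroids <- c(centroids[seq_len(i - 1)], merged,
                   centroids[seq_along(centroids) > i + 1])
    weights <- c(weights[seq_len(i - 1)], sum(weights[c(i, i + 1)]),
                 weights[seq_along(weights) > i + 1])
  }
  moi_list(centroids, tolerance = tolerance)
}

# ---- molecular fingerprints ------------------------------------------------

#' Fingerprint backends
#'
#' Structure fingerprinting is a pluggable contract: a backend is a
#' function mapping one SMILES string to a fixed-length non-negative
#' integer vector, carrying a `fp_length` attribute. Two backends ship
#' with the package:
#'
#' * `fp_backend_hash(n_bits)` — a deterministic hashed substring-count
#'   fingerprint (default length 790). It requires no chemistry toolkit
#'   and is the default for synthetic work; it is *not* a chemically
#'   meaningful descriptor.
#' * `fp_backend_chemminer(n_bits)` — atom-pair-derived binary keys via
#'   ChemmineR (`smiles2sdf` → `sdf2ap` → `desc2fp`), the canonical
#'   choice when real structures are analyzed. Requires the ChemmineR
#'   package.
#'
#' @param n_bits fingerprint length.
#' @return A backend function for [fingerprint()].
#' @export
fp_backend_hash <- function(n_bits = 790L) {
  force(n_bits)
  backend <- function(smiles) {
    check_smiles(smiles)
    v <- integer(n_bits)
    # counts of hashed character n-grams (n = 1..3) of the SMILES string
    chars <- strsplit(smiles, "")[[1]]
    for (n in 1:3) {
      if (length(chars) < n) break
      grams <- vapply(seq_len(length(chars) - n + 1L),
                      function(i) paste(chars[i:(i + n - 1L)], collapse = ""),
                      character(1))
      idx <- vapply(grams, hash_string, integer(1), mod = n_bits) + 1L
      for (j in idx) v[j] <- v[j] + 1L
    }
    structure(v, fp_length = n_bits)
  }
  attr(backend, "fp_length") <- n_bits
  backend
}

# FNV-1a 32-bit, kept in double space to avoid integer overflow
hash_string <- function(s, mod) {
  h <- 2166136261
  for (code in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31 - 2^30), code) + 2^30  # fold into range
    h <- (h * 16777619) %% 2^31
  }
  as.integer(h %% mod)
}

check_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(smiles)) {
    stop("SMILES must be a single non-empty string.", call. = FALSE)
  }
  if (grepl("[^A-Za-z0-9@+\\-\\[\\]()=#$:/\\\\%.*]", smiles, perl = TRUE)) {
    stop("Cannot parse structure: '", smiles, "'", call. = FALSE)
  }
  n_of <- function(ch) nchar(smiles) - nchar(gsub(ch, "", smiles, fixed = TRUE))
  ok_paren <- n_of("(") == n_of(")")
  ok_brack <- n_of("[") == n_of("]")
  if (!ok_paren || !ok_brack) {
    stop("Cannot parse structure (unbalanced brackets): '", smiles, "'",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' @rdname fp_backend_hash
#' @export
fp_backend_chemminer <- function(n_bits = 1024L) {
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    stop("The ChemmineR backend requires the ChemmineR package.", call. = FALSE)
  }
  force(n_bits)
  # the most frequent atom-pair keys shipped with ChemmineR
  key_env <- new.env(parent = emptyenv())
  utils::data("apfp", package = "ChemmineR", envir = key_env)
  descnames <- as.character(key_env$apfp$AP)[seq_len(n_bits)]
  backend <- function(smiles) {
    check_smiles(smiles)
    sdf <- tryCatch(
      suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, "query"))),
      error = function(e) stop("Cannot parse structure: '", smiles, "'",
                               call. = FALSE))
    ap <- suppressMessages(ChemmineR::sdf2ap(sdf))
    fp <- ChemmineR::desc2fp(ap, descnames = descnames, type = "matrix")
    structure(as.integer(fp[1, ]), fp_length = n_bits)
  }
  attr(backend, "fp_length") <- n_bits
  backend
}

#' Compute a molecular fingerprint
#'
#' @param smiles a single SMILES string.
#' @param backend a backend function (see [fp_backend_hash()]).
#' @return Integer count vector of the backend's fixed length.
#' @export
fingerprint <- function(smiles, backend = fp_backend_hash()) {
  backend(smiles)
}

#' Fingerprint a compound table
#'
#' @param compounds tibble with `inchikey` and `smiles` columns.
#' @inheritParams fingerprint
#' @return The input tibble with a matrix column `fp`.
#' @export
fingerprint_compounds <- function(compounds, backend = fp_backend_hash()) {
  stopifnot(all(c("inchikey", "smiles") %in% names(compounds)))
  fps <- purrr::map(compounds$smiles, backend)
  compounds$fp <- do.call(rbind, fps)
  compounds
}

# ---- leverage applicability domain -----------------------------------------

#' Fit a leverage-based applicability domain
#'
#' The applicability domain (AD) of a retention model is defined through
#' leverage: h = x' (X'X)^-1 x for query vector x against the training
#' design matrix X. The AD threshold is the 95% leverage of the training
#' data — the smallest training leverage at or below which at least 95% of
#' training rows fall (type-1 empirical quantile) — so by construction at
#' least 95% of training rows are in-domain. A pseudo-inverse is used when
#' X'X is singular.
#'
#' @param X numeric training design matrix (n rows, p features).
#' @param quantile_level quantile of training leverages used as threshold
#'   (default 0.95).
#' @return An object of class `nta_ad` with elements `gram_inverse`,
#'   `threshold`, `training_leverage`, `p`.
#' @export
fit_ad <- function(X, quantile_level = 0.95) {
  X <- as.matrix(X)
  if (nrow(X) == 0L) stop("Cannot fit an applicability domain on empty X.",
                          call. = FALSE)
  if (nrow(X) <= ncol(X)) {
    warning("n <= p: leverage computed through a pseudo-inverse; ",
            "the applicability domain will be permissive.", call. = FALSE)
  }
  gram <- crossprod(X)
  gram_inv <- tryCatch(solve(gram), error = function(e) MASS::ginv(gram))
  h <- rowSums((X %*% gram_inv) * X)
  h <- pmax(h, 0)
  threshold <- as.numeric(stats::quantile(h, quantile_level, type = 1, names = FALSE))
  structure(list(gram_inverse = gram_inv, threshold = threshold,
                 training_leverage = h, p = ncol(X)),
            class = "nta_ad")
}

#' @export
print.nta_ad <- function(x, ...) {
  cat("<nta_ad> p =", x$p, "| threshold =", signif(x$threshold, 4),
      "| training n =", length(x$training_leverage), "\n")
  invisible(x)
}

#' Leverage of query vectors
#'
#' @param ad an `nta_ad` object from [fit_ad()].
#' @param x a numeric vector of length p, or a matrix with p columns.
#' @return Numeric vector of leverages (h >= 0), one per query row.
#' @export
leverage <- function(ad, x) {
  stopifnot(inherits(ad, "nta_ad"))
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(x) != ad$p) {
    stop("Query has ", ncol(x), " features; the applicability domain expects ",
         ad$p, ".", call. = FALSE)
  }
  pmax(rowSums((x %*% ad$gram_inverse) * x), 0)
}

#' @rdname leverage
#' @return [in_domain()] returns a logical vector: leverage at or below
#'   the AD threshold.
#' @export
in_domain <- function(ad, x) {
  leverage(ad, x) <= ad$threshold
}
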