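#' Match one query spectrum against one reference spectrum
#'
#' Computes the seven matching parameters summed into the final library
#' matching score. Fragments are matched greedily, closest mass
#' difference first, one-to-one, within `frag_tol`. The parameters are:
#'
#' * `RefMatchFragRatio` — matched fragments / reference peaks
#' * `QueryMatchFragRatio` — matched fragments / query peaks
#' * `MS1Error` — absolute precursor difference in ppm (symmetric,
#'   relative to the mean precursor m/z)
#' * `MS2ErrorMean`, `MS2ErrorStd` — mean and SD of matched-fragment
#'   mass differences (query minus reference, Da)
#' * `IntensityDotScore` — cosine similarity of matched intensities
#' * `DirectMatchFragRatio` — fragments matched within `frag_tol / 2`,
#'   over reference peaks
#'
#' The final score sums seven terms, each in \[0, 1\]: the three
#' ratio-type parameters, the intensity cosine, and the three error
#' statistics (`|MS2ErrorMean|`, `MS1Error`, `MS2ErrorStd`) each mapped
#' through `1 - min(error / tolerance, 1)`. `FinalScoreRatio =
#' final_score / 7`. With no matched fragments the fragment-error
#' statistics take their worst value (the tolerance), so only the
#' precursor term can contribute.
#'
#' @param query,reference one-row `nta_spectra` tibbles with normalized
#'   peaks and equal polarity.
#' @param frag_tol fragment matching tolerance (Da, default 0.01).
#' @param ms1_tol precursor tolerance (ppm, default 5).
#' @return A one-row tibble with ids, the seven parameters,
#'   `final_score` and `FinalScoreRatio`.
#' @export
match_pair <- function(query, reference, frag_tol = 0.01, ms1_tol = 5) {
  stopifnot(nrow(query) == 1L, nrow(reference) == 1L)
  if (query$polarity != reference$polarity) {
    stop("Polarity mismatch between query and reference spectra.", call. = FALSE)
  }
  p <- match_params(query$peaks[[1]]$mz, query$peaks[[1]]$intensity,
                    reference$peaks[[1]]$mz, reference$peaks[[1]]$intensity,
                    query$precursor_mz, reference$precursor_mz,
                    frag_tol, ms1_tol)
  tibble::tibble(query_id = query$spectrum_id,
                 reference_id = reference$spectrum_id,
                 reference_compound = reference$compound_id,
                 !!!p)
}

# numeric core shared by match_pair() and the batch search
match_params <- function(qmz, qint, rmz, rint, qprec, rprec, frag_tol, ms1_tol) {
  nq <- length(qmz); nr <- length(rmz)
  pairs <- greedy_peak_match(qmz, rmz, frag_tol)
  m <- nrow(pairs)
  dmz <- if (m) qmz[pairs[, 1]] - rmz[pairs[, 2]] else numeric(0)
  ms1_error <- abs(qprec - rprec) / mean(c(qprec, rprec)) * 1e6
  if (m == 0L) {
    ms2_mean <- frag_tol   # worst case: zero contribution to the score
    ms2_std <- frag_tol
    int_dot <- 0
    direct <- 0
  } else {
    ms2_mean <- mean(dmz)
    ms2_std <- if (m >= 2L) stats::sd(dmz) else 0
    qi <- qint[pairs[, 1]]; ri <- rint[pairs[, 2]]
    int_dot <- if (sum(qi) == 0 || sum(ri) == 0) 0 else
      sum(qi * ri) / sqrt(sum(qi^2) * sum(ri^2))
    direct <- sum(abs(dmz) <= frag_tol / 2) / max(nr, 1L)
  }
  ref_ratio <- if (nr) m / nr else 0
  query_ratio <- if (nq) m / nq else 0
  score <- ref_ratio + query_ratio + int_dot + direct +
    (1 - min(abs(ms2_mean) / frag_tol, 1)) +
    (1 - min(ms1_error / ms1_tol, 1)) +
    (1 - min(ms2_std / frag_tol, 1))
  list(RefMatchFragRatio = ref_ratio,
       QueryMatchFragRatio = query_ratio,
       MS1Error = ms1_error,
       MS2ErrorMean = ms2_mean,
       MS2ErrorStd = ms2_std,
       IntensityDotScore = int_dot,
       DirectMatchFragRatio = direct,
       n_matched = m,
       final_score = score,
       FinalScoreRatio = score / 7)
}

# one-to-one greedy assignment by ascending |delta mz|; returns a
# 2-column matrix of (query index, reference index)
greedy_peak_match <- function(qmz, rmz, frag_tol) {
  if (length(qmz) == 0L || length(rmz) == 0L) {
    return(matrix(integer(0), ncol = 2))
  }
  d <- abs(outer(qmz, rmz, "-"))
  cand <- which(d <= frag_tol, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(matrix(integer(0), ncol = 2))
  cand <- cand[order(d[cand], cand[, 1], cand[, 2]), , drop = FALSE]
  used_q <- logical(length(qmz)); used_r <- logical(length(rmz))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    qi <- cand[i, 1]; ri <- cand[i, 2]
    if (!used_q[qi] && !used_r[ri]) {
      keep[i] <- TRUE
      used_q[qi] <- TRUE
      used_r[ri] <- TRUE
    }
  }
  cand[keep, , drop = FALSE]
}

#' Search query spectra against a reference library
#'
#' Scores every query/reference pair (optionally restricted to references
#' whose precursor lies within `precursor_window` Da of the query) and
#' splits the results at the matching-score gate: matches with
#' `FinalScoreRatio >= min_score_ratio` are the accepted candidates
#' (label `"unknown"`, to be adjudicated by the true-positive-probability
#' classifier), matches below the gate are pre-labeled `"TN"`.
#'
#' @param queries,library `nta_spectra` tibbles (library non-empty).
#' @param min_score_ratio acceptance gate on `FinalScoreRatio`
#'   (default 0.5).
#' @param frag_tol,ms1_tol matching tolerances, see [match_pair()].
#' @param precursor_window optional precursor prefilter (Da);
#'   `Inf` (default) scores all pairs.
#' @return A tibble of matches — accepted rows first, each block sorted
#'   by descending `FinalScoreRatio` — with an `accepted` flag and a
#'   `label` column.
#' @export
search_library <- function(queries, library, min_score_ratio = 0.5,
                           frag_tol = 0.01, ms1_tol = 5,
                           precursor_window = Inf) {
  stopifnot(is.data.frame(library))
  if (nrow(library) == 0L) stop("Reference library is empty.", call. = FALSE)
  rows <- vector("list", nrow(queries))
  for (i in seq_len(nrow(queries))) {
    cand <- which(library$polarity == queries$polarity[i] &
                    abs(library$precursor_mz - queries$precursor_mz[i]) <=
                      precursor_window)
    if (length(cand) == 0L) next
    res <- purrr::map_dfr(cand, function(j) {
      tibble::tibble(
        query_id = queries$spectrum_id[i],
        reference_id = library$spectrum_id[j],
        reference_compound = library$compound_id[j],
        !!!match_params(queries$peaks[[i]]$mz, queries$peaks[[i]]$intensity,
                        library$peaks[[j]]$mz, library$peaks[[j]]$intensity,
                        queries$precursor_mz[i], library$precursor_mz[j],
                        frag_tol, ms1_tol))
    })
    rows[[i]] <- res
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out$accepted <- logical(0)
    out$label <- character(0)
    return(out)
  }
  out$accepted <- out$FinalScoreRatio >= min_score_ratio
  out$label <- ifelse(out$accepted, "unknown", "TN")
  dplyr::arrange(out, dplyr::desc(.data$accepted),
                 dplyr::desc(.data$FinalScoreRatio))
}
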