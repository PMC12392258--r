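#' Generate a synthetic screening world
#'
#' Builds a self-contained, seed-reproducible universe of compounds and
#' positive-mode MS/MS spectra with the statistical structure the
#' annotation pipeline assumes, so every stage is testable without
#' instrument data:
#'
#' * Each compound carries a 16-bit latent descriptor vector; its true
#'   retention-time index is a weighted sum of the bits plus Gaussian
#'   noise, so retention is a smooth function of structure.
#' * A fixed 200-mass neutral-loss vocabulary acts as the fragment
#'   grammar: six core losses are present in every compound (a shared
#'   backbone), each descriptor bit switches on two characteristic
#'   losses, and two further losses per compound are idiosyncratic.
#'   Spectra realize these losses with m/z jitter, log-normal
#'   intensities and optional fragment dropout.
#' * Fingerprints are a deterministic 790-length count expansion of the
#'   descriptor bits, so the fingerprint and CNL retention models learn
#'   the same latent variable.
#' * Compounds are organized in isobaric analog families: members of a
#'   family share an exact monoisotopic mass and most descriptor bits
#'   (3 to 5 bits flipped from the family pattern), which is what makes
#'   wrong-candidate matches score well while differing in retention.
#'
#' Every generated spectrum passes the 2-MOI minimum by construction.
#'
#' @param n_compounds number of compounds (>= 2).
#' @param spectra_per_compound replicate spectra per compound.
#' @param noise list with elements `mz_sd` (fragment and precursor m/z
#'   jitter SD, Da), `intensity_sd` (log-normal intensity SD),
#'   `rti_sd` (retention noise SD, harmonized RTI units) and `dropout`
#'   (per-fragment omission probability). Defaults emulate a
#'   well-calibrated high-resolution instrument:
#'   `list(mz_sd = 0.001, intensity_sd = 0.3, rti_sd = 25, dropout = 0.15)`.
#' @param seed integer seed; regeneration with the same seed is
#'   bit-identical.
#' @return An object of class `nta_world`: a list with `compounds`
#'   (tibble with matrix columns `descriptor` and `fp`), `spectra`
#'   (an `nta_spectra` tibble), `moi` (the full loss vocabulary as a
#'   [moi_list()]), `weights`, `noise`, `seed`.
#' @export
generate_world <- function(n_compounds = 500L, spectra_per_compound = 3L,
                           noise = list(), seed = 1L) {
  if (n_compounds < 2L) stop("Need at least 2 compounds.", call. = FALSE)
  noise <- utils::modifyList(
    list(mz_sd = 0.001, intensity_sd = 0.3, rti_sd = 25, dropout = 0.15),
    noise
  )
  bad <- vapply(noise, function(v) !is.numeric(v) || v < 0, logical(1))
  if (any(bad) || noise$dropout >= 1) {
    stop("Noise parameters must be non-negative (dropout < 1).", call. = FALSE)
  }
  old <- get0(".Random.seed", globalenv())
  on.exit(restore_rng(old))
  set.seed(seed)

  n_bits <- 16L
  vocab_size <- 200L
  n_core <- 6L
  # loss vocabulary: an even grid over 20-130 Da with a small jitter;
  # spacing stays > 0.15 Da so MOI bins never overlap at tol 0.01
  vocab <- seq(20, 130, length.out = vocab_size) +
    stats::runif(vocab_size, -0.2, 0.2)
  vocab <- sort(vocab)
  weights <- stats::runif(n_bits, 50, 150)  # RTI contribution per bit

  # analog families sharing an exact monoisotopic mass and most bits
  n_groups <- max(2L, ceiling(n_compounds / 12))
  group_mass <- stats::runif(n_groups, 150, 450)
  group_bits <- matrix(stats::rbinom(n_groups * n_bits, 1, 0.5),
                       nrow = n_groups)
  group <- rep(seq_len(n_groups), length.out = n_compounds)

  descriptor <- matrix(0L, n_compounds, n_bits)
  for (i in seq_len(n_compounds)) {
    d <- group_bits[group[i], ]
    flip <- sample.int(n_bits, sample(3:5, 1))
    d[flip] <- 1L - d[flip]
    descriptor[i, ] <- d
  }

  rti_latent <- as.numeric(descriptor %*% weights)
  true_rti <- rti_latent + stats::rnorm(n_compounds, 0, noise$rti_sd)

  # deterministic fingerprint expansion: fixed 0/1 hash map, 16 -> 790
  fp_map <- matrix(stats::rbinom(n_bits * 790L, 1, 0.15), nrow = n_bits)
  fp <- descriptor %*% fp_map
  storage.mode(fp) <- "integer"

  inchikey <- synthetic_inchikeys(n_compounds)
  smiles <- apply(descriptor, 1, function(d)
    paste0("C", paste(ifelse(d == 1, "CO", "CC"), collapse = ""), "N"))

  # characteristic losses: 6 core + 2 per active bit + 2 idiosyncratic
  bit_losses <- lapply(seq_len(n_bits), function(j) vocab[n_core + c(2L * j - 1L, 2L * j)])
  extra_pool <- (n_core + 2L * n_bits + 1L):vocab_size
  losses <- lapply(seq_len(n_compounds), function(i) {
    sort(c(vocab[seq_len(n_core)],
           unlist(bit_losses[descriptor[i, ] == 1L]),
           vocab[sample(extra_pool, 2L)]))
  })

  compounds <- tibble::tibble(
    inchikey = inchikey, smiles = smiles, group = group,
    monoisotopic_mass = group_mass[group], true_rti = true_rti
  )
  compounds$descriptor <- descriptor
  compounds$fp <- fp

  n_spec <- n_compounds * spectra_per_compound
  ids <- character(n_spec)
  prec <- numeric(n_spec)
  pk <- vector("list", n_spec)
  comp_of <- integer(n_spec)
  s <- 0L
  for (i in seq_len(n_compounds)) {
    li <- losses[[i]]
    base_int <- c(rep(1, n_core), rep(0.5, length(li) - n_core))
    prec_true <- compounds$monoisotopic_mass[i] + PROTON_MASS
    for (r in seq_len(spectra_per_compound)) {
      s <- s + 1L
      keep <- stats::runif(length(li)) >= noise$dropout
      keep[1:2] <- TRUE  # every spectrum keeps >= 2 core losses (2-MOI rule)
      p_obs <- prec_true + stats::rnorm(1, 0, noise$mz_sd)
      mz <- p_obs - li[keep] + stats::rnorm(sum(keep), 0, noise$mz_sd)
      int <- base_int[keep] * exp(stats::rnorm(sum(keep), 0, noise$intensity_sd))
      ids[s] <- sprintf("%s_sp%02d", compounds$inchikey[i], r)
      prec[s] <- p_obs
      pk[[s]] <- tibble::tibble(mz = mz, intensity = int)
      comp_of[s] <- i
    }
  }
  spectra <- spectra_tbl(
    spectrum_id = ids, precursor_mz = prec, peaks = pk,
    polarity = "positive", adduct = "[M+H]+",
    compound_id = compounds$inchikey[comp_of],
    monoisotopic_mass = compounds$monoisotopic_mass[comp_of]
  )
  spectra <- normalize_spectra(spectra)

  structure(list(compounds = compounds, spectra = spectra,
                 moi = moi_list(vocab, tolerance = 0.01),
                 weights = weights, noise = noise, seed = seed),
            class = "nta_world")
}

#' @export
print.nta_world <- function(x, ...) {
  cat("<nta_world> ", nrow(x$compounds), " compounds x ",
      nrow(x$spectra) / nrow(x$compounds), " spectra | seed ", x$seed, "\n",
      sep = "")
  invisible(x)
}

# InChIKey-shaped synthetic identifiers (14-10-1 uppercase blocks)
synthetic_inchikeys <- function(n) {
  repeat {
    keys <- vapply(seq_len(n), function(i) {
      paste0(paste(sample(LETTERS, 14, replace = TRUE), collapse = ""), "-",
             paste(sample(LETTERS, 10, replace = TRUE), collapse = ""), "-N")
    }, character(1))
    if (!anyDuplicated(keys)) return(keys)
  }
}

#' Generate a labeled spectral-match benchmark
#'
#' Runs the full front end of the pipeline on a synthetic world and emits
#' the labeled six-feature table the true-positive-probability classifier
#' trains on. One spectrum per compound becomes the reference library;
#' the remaining spectra are queries. True-positive rows pair each query
#' with its own compound's reference spectrum; true-negative rows pair it
#' with wrong candidate structures sampled (via the
#' [make_semisynthetic_tn()] construction) from the query compound's
#' isobaric analog family. The retention-index error feature combines a
#' fingerprint-model prediction for the candidate structure with a
#' CNL-model prediction for the query spectrum, so negatives inherit the
#' wrong structure's retention.
#'
#' @param world an [generate_world()] object with at least 2 spectra per
#'   compound.
#' @param n_tn_per_spectrum decoy candidates per query spectrum.
#' @param seed integer seed (decoy sampling and model fits).
#' @param frag_tol,ms1_tol matching tolerances, see [match_pair()].
#' @param min_score_ratio score gate recorded in the `accepted` column.
#' @param mass_tol accurate-mass window for decoy candidates (Da).
#' @return A tibble with the six classifier features
#'   (`RefMatchFragRatio`, `MS1Error`, `MS2ErrorStd`, `FinalScoreRatio`,
#'   `monoisotopic_mass`, `rti_error`), the 0/1 `label`, match
#'   identifiers and the `accepted` gate flag. The fitted retention
#'   models are attached as attributes `model_mf` and `model_cnl`;
#'   `attr(, "class_ratio")` reports the TN:TP ratio.
#' @export
generate_match_benchmark <- function(world, n_tn_per_spectrum = 9L, seed = 1L,
                                     frag_tol = 0.01, ms1_tol = 5,
                                     min_score_ratio = 0.5, mass_tol = 0.01) {
  stopifnot(inherits(world, "nta_world"))
  match_benchmark_tbl(world$spectra, world$compounds, world$moi,
                      n_tn_per_spectrum = n_tn_per_spectrum, seed = seed,
                      frag_tol = frag_tol, ms1_tol = ms1_tol,
                      min_score_ratio = min_score_ratio, mass_tol = mass_tol)
}

# shared core: works for any labeled spectrum corpus, not only worlds.
# `compounds` needs inchikey, monoisotopic_mass, true_rti and a matrix
# column fp; spectra must carry compound_id.
match_benchmark_tbl <- function(spectra, compounds, moi,
                                n_tn_per_spectrum = 9L, seed = 1L,
                                frag_tol = 0.01, ms1_tol = 5,
                                min_score_ratio = 0.5, mass_tol = 0.01) {
  first_of <- !duplicated(spectra$compound_id)
  library_sp <- spectra[first_of, ]
  queries <- spectra[!first_of, ]
  if (nrow(queries) == 0L) {
    stop("Need >= 2 spectra for some compound to form query/reference pairs.",
         call. = FALSE)
  }

  # retention models: structure -> RTI and spectrum -> RTI
  model_mf <- train_rti(compounds$fp, compounds$true_rti,
                        feature_space = "fingerprint", seed = seed)
  feats <- cnl_features(spectra, moi, drop_below_min = FALSE)
  X_cnl <- cnl_design_matrix(feats)
  target <- compounds$true_rti[match(spectra$compound_id, compounds$inchikey)]
  model_cnl <- train_rti(X_cnl, target, feature_space = "cnl", seed = seed)

  rti_mf_all <- stats::setNames(predict_rti(model_mf, compounds$fp)$rti,
                                compounds$inchikey)
  q_feats <- cnl_features(queries, moi, drop_below_min = FALSE)
  rti_cnl_q <- stats::setNames(predict_rti(model_cnl, cnl_design_matrix(q_feats))$rti,
                               q_feats$spectrum_id)
  mass_of <- stats::setNames(compounds$monoisotopic_mass, compounds$inchikey)

  old <- get0(".Random.seed", globalenv())
  on.exit(restore_rng(old))
  set.seed(seed)

  ref_idx_of <- stats::setNames(seq_len(nrow(library_sp)),
                                library_sp$compound_id)

  rows <- vector("list", nrow(queries))
  for (i in seq_len(nrow(queries))) {
    truth <- queries$compound_id[i]
    pool <- compounds$inchikey[compounds$inchikey != truth &
                                 abs(mass_of - mass_of[[truth]]) <= mass_tol]
    if (length(pool) == 0L) pool <- setdiff(compounds$inchikey, truth)
    decoys <- sample(pool, min(n_tn_per_spectrum, length(pool)))
    cands <- c(truth, decoys)
    res <- purrr::map_dfr(cands, function(ck) {
      j <- ref_idx_of[[ck]]
      p <- match_params(queries$peaks[[i]]$mz, queries$peaks[[i]]$intensity,
                        library_sp$peaks[[j]]$mz, library_sp$peaks[[j]]$intensity,
                        queries$precursor_mz[i], library_sp$precursor_mz[j],
                        frag_tol, ms1_tol)
      tibble::tibble(
        query_id = queries$spectrum_id[i],
        compound = ck,
        label = as.integer(ck == truth),
        RefMatchFragRatio = p$RefMatchFragRatio,
        MS1Error = p$MS1Error,
        MS2ErrorStd = p$MS2ErrorStd,
        FinalScoreRatio = p$FinalScoreRatio,
        monoisotopic_mass = mass_of[[ck]],
        rti_error = rti_error(rti_mf_all[[ck]],
                              rti_cnl_q[[queries$spectrum_id[i]]])
      )
    })
    rows[[i]] <- res
  }
  out <- dplyr::bind_rows(rows)
  out$accepted <- out$FinalScoreRatio >= min_score_ratio
  attr(out, "model_mf") <- model_mf
  attr(out, "model_cnl") <- model_cnl
  attr(out, "class_ratio") <- sum(out$label == 0) / sum(out$label == 1)
  out
}

#' Assemble classifier feature rows from search results
#'
#' Joins library-search matches with the two retention predictions into
#' the six-feature table consumed by [train_ptp()] / [predict_ptp()]:
#' the four matching parameters plus the candidate's monoisotopic mass
#' and the retention-index error `RTI_MF - RTI_CNL`.
#'
#' @param matches tibble from [search_library()] (columns `query_id`,
#'   `reference_compound`, `RefMatchFragRatio`, `MS1Error`,
#'   `MS2ErrorStd`, `FinalScoreRatio`).
#' @param rti_mf named vector: fingerprint-model RTI per candidate
#'   compound (InChIKey).
#' @param rti_cnl named vector: CNL-model RTI per query spectrum id.
#' @param mass named vector: monoisotopic mass per candidate compound.
#' @return The matches with `monoisotopic_mass` and `rti_error` columns
#'   appended.
#' @export
build_match_features <- function(matches, rti_mf, rti_cnl, mass) {
  stopifnot(all(c("query_id", "reference_compound", "RefMatchFragRatio",
                  "MS1Error", "MS2ErrorStd", "FinalScoreRatio") %in%
                  names(matches)))
  unknown <- setdiff(matches$reference_compound, names(rti_mf))
  if (length(unknown)) {
    stop("No fingerprint RTI prediction for compound(s): ",
         paste(utils::head(unknown, 3), collapse = ", "), call. = FALSE)
  }
  matches$monoisotopic_mass <- unname(mass[matches$reference_compound])
  matches$rti_error <- rti_error(unname(rti_mf[matches$reference_compound]),
                                 unname(rti_cnl[matches$query_id]))
  matches
}
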