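#' Run configuration
#'
#' Builds the validated configuration consumed by [run_pipeline()] and
#' the command-line entry point. Every tunable of the pipeline lives
#' here; values round-trip losslessly through [write_run_config()] /
#' [read_run_config()] (YAML).
#'
#' @param seed master integer seed; every stochastic step derives its
#'   seed from it.
#' @param out_dir output directory for result files.
#' @param frag_tol fragment matching tolerance (Da, in (0, 1\]).
#' @param ms1_tol precursor tolerance (ppm, in (0, 100\]).
#' @param precursor_window precursor prefilter for the library search
#'   (Da).
#' @param min_score_ratio matching-score gate in \[0, 1\].
#' @param ptp_threshold hit shortlisting threshold on average P(TP).
#' @param replication_factor positive-row replication for class balance.
#' @param r_threshold Pearson cut for feature pruning.
#' @param algorithm classifier algorithm (see [train_ptp()]).
#' @param train_fraction benchmark train fraction in (0, 1).
#' @param simulate list of [generate_world()] arguments
#'   (`n_compounds`, `spectra_per_compound`, `noise`), or `NULL` when
#'   file inputs are used.
#' @param inputs list with paths `queries_msp`, `library_msp`,
#'   `compounds_csv` (used when `simulate` is `NULL`; the compound table
#'   must carry true RTI values).
#' @param n_tn_per_spectrum decoy candidates per spectrum for classifier
#'   training.
#' @return A list of class `nta_config`.
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("ntaprob_"),
                       frag_tol = 0.01, ms1_tol = 5, precursor_window = 0.5,
                       min_score_ratio = 0.5, ptp_threshold = 0.5,
                       replication_factor = 10L, r_threshold = 0.80,
                       algorithm = "knn", train_fraction = 0.7,
                       simulate = list(n_compounds = 60L,
                                       spectra_per_compound = 3L),
                       inputs = NULL, n_tn_per_spectrum = 9L) {
  cfg <- list(seed = as.integer(seed), out_dir = out_dir,
              frag_tol = frag_tol, ms1_tol = ms1_tol,
              precursor_window = precursor_window,
              min_score_ratio = min_score_ratio,
              ptp_threshold = ptp_threshold,
              replication_factor = as.integer(replication_factor),
              r_threshold = r_threshold, algorithm = algorithm,
              train_fraction = train_fraction,
              simulate = simulate, inputs = inputs,
              n_tn_per_spectrum = as.integer(n_tn_per_spectrum))
  validate_config(cfg)
}

validate_config <- function(cfg) {
  needed <- c("seed", "out_dir", "frag_tol", "ms1_tol", "precursor_window",
              "min_score_ratio", "ptp_threshold", "replication_factor",
              "r_threshold", "algorithm", "train_fraction",
              "n_tn_per_spectrum")
  absent <- needed[vapply(needed, function(k) is.null(cfg[[k]]), logical(1))]
  if (length(absent)) {
    stop("Config is missing field(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(
    is.numeric(cfg$seed),
    cfg$frag_tol > 0, cfg$frag_tol <= 1,
    cfg$ms1_tol > 0, cfg$ms1_tol <= 100,
    cfg$min_score_ratio >= 0, cfg$min_score_ratio <= 1,
    cfg$ptp_threshold >= 0, cfg$ptp_threshold <= 1,
    cfg$replication_factor >= 1,
    cfg$r_threshold > 0, cfg$r_threshold <= 1,
    cfg$train_fraction > 0, cfg$train_fraction < 1,
    cfg$algorithm %in% c("knn", "logistic", "tree", "forest")
  )
  if (is.null(cfg$simulate) && is.null(cfg$inputs)) {
    stop("Config needs either a `simulate` block or an `inputs` block.",
         call. = FALSE)
  }
  structure(cfg, class = "nta_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("Config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  defaults <- unclass(run_config())
  cfg <- defaults
  for (k in names(raw)) cfg[[k]] <- raw[[k]]
  if (!is.null(raw$inputs) && is.null(raw$simulate)) cfg["simulate"] <- list(NULL)
  # restore canonical field order and keep explicit NULL slots
  cfg <- stats::setNames(lapply(names(defaults), function(k) cfg[[k]]),
                         names(defaults))
  validate_config(cfg)
}

#' @rdname run_config
#' @param config an `nta_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full annotation pipeline
#'
#' Executes the complete workflow on one configuration: acquire spectra
#' and compounds (simulated world or MSP/CSV inputs), train the
#' fingerprint and CNL retention models, build the labeled match
#' benchmark and train the P(TP) classifier on its training split,
#' search the query spectra against the reference library, score
#' accepted matches with P(TP) (sub-gate matches get P(TP) = 0),
#' aggregate per-compound hits, and compute per-tensor identification
#' probabilities. All results are written to `config$out_dir` as CSV and
#' JSON; reruns with the same seed are byte-identical.
#'
#' @param config an [run_config()] object (or a list coercible to one).
#' @return Invisibly, a list with `identifications`, `hits`, `matches`,
#'   `metrics`, `paths`, `config`.
#' @export
run_pipeline <- function(config = run_config()) {
  cfg <- validate_config(unclass(config))

  if (!is.null(cfg$simulate)) {
    world <- do.call(generate_world,
                     c(cfg$simulate, list(seed = cfg$seed)))
    spectra <- world$spectra
    compounds <- world$compounds
    moi <- world$moi
  } else {
    queries_in <- read_msp(cfg$inputs$queries_msp)
    library_in <- read_msp(cfg$inputs$library_msp)
    compounds <- read_compound_table(cfg$inputs$compounds_csv)
    compounds <- compounds[is.finite(compounds$rti), ]
    if (nrow(compounds) < 2L) {
      stop("Compound table must provide true RTI values for >= 2 compounds.",
           call. = FALSE)
    }
    names(compounds)[names(compounds) == "rti"] <- "true_rti"
    compounds <- fingerprint_compounds(compounds)
    spectra <- normalize_spectra(dplyr::bind_rows(library_in, queries_in))
    spectra <- spectra[!is.na(spectra$compound_id), ]
    moi <- select_mois(spectra, min_frequency = 0.02,
                       tolerance = cfg$frag_tol)
  }

  # classifier benchmark (also trains the two retention models)
  bench <- match_benchmark_tbl(
    spectra, compounds, moi,
    n_tn_per_spectrum = cfg$n_tn_per_spectrum, seed = cfg$seed,
    frag_tol = cfg$frag_tol, ms1_tol = cfg$ms1_tol,
    min_score_ratio = cfg$min_score_ratio
  )
  model_mf <- attr(bench, "model_mf")
  model_cnl <- attr(bench, "model_cnl")

  split <- stratified_label_split(bench$label, cfg$train_fraction,
                                  seed = cfg$seed + 1L)
  train <- bench[split$train_idx, ]
  test <- bench[split$test_idx, ]
  retained <- prune_correlated(train, r_threshold = cfg$r_threshold)
  clf <- train_ptp(balance_by_replication(train, cfg$replication_factor),
                   algorithm = cfg$algorithm, features = retained,
                   seed = cfg$seed + 2L)

  test_ptp <- predict_ptp(clf, test)
  counts <- confusion_counts(test$label, as.integer(test_ptp >= cfg$ptp_threshold))
  calibration <- calibrate_fdr(clf, test)
  targets <- attr(calibration, "targets")

  # annotate the query spectra against the per-compound reference library
  first_of <- !duplicated(spectra$compound_id)
  library_sp <- spectra[first_of, ]
  queries <- spectra[!first_of, ]
  matches <- search_library(queries, library_sp,
                            min_score_ratio = cfg$min_score_ratio,
                            frag_tol = cfg$frag_tol, ms1_tol = cfg$ms1_tol,
                            precursor_window = cfg$precursor_window)
  if (nrow(matches) > 0L) {
    rti_mf <- stats::setNames(predict_rti(model_mf, compounds$fp)$rti,
                              compounds$inchikey)
    q_feats <- cnl_features(queries, moi, drop_below_min = FALSE)
    rti_cnl <- stats::setNames(
      predict_rti(model_cnl, cnl_design_matrix(q_feats))$rti,
      q_feats$spectrum_id)
    mass <- stats::setNames(compounds$monoisotopic_mass, compounds$inchikey)
    matches <- build_match_features(matches, rti_mf, rti_cnl, mass)
    matches$ptp <- 0
    if (any(matches$accepted)) {
      matches$ptp[matches$accepted] <-
        predict_ptp(clf, matches[matches$accepted, ])
    }
  }

  scored <- dplyr::transmute(matches, tensor_id = .data$query_id,
                             compound = .data$reference_compound,
                             ptp = .data$ptp)
  identifications <- identify_features(scored, threshold = cfg$ptp_threshold)
  hits <- attr(identifications, "hits")

  metrics <- list(
    classifier = list(algorithm = cfg$algorithm,
                      features = retained,
                      mcc = mcc(counts),
                      weighted_f1 = weighted_f1(counts),
                      recall = recall_score(counts),
                      fdr = fdr_score(counts),
                      n_train = nrow(train), n_test = nrow(test)),
    fdr_thresholds = targets,
    panel = panel_summary(identifications),
    seed = cfg$seed
  )

  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    matches = file.path(cfg$out_dir, "matches.csv"),
    features = file.path(cfg$out_dir, "match_features.csv"),
    hits = file.path(cfg$out_dir, "hits.csv"),
    identifications = file.path(cfg$out_dir, "identifications.csv"),
    identifications_json = file.path(cfg$out_dir, "identifications.json"),
    metrics = file.path(cfg$out_dir, "metrics.json"),
    config = file.path(cfg$out_dir, "config.yaml")
  )
  readr::write_csv(matches, paths$matches)
  readr::write_csv(dplyr::select(bench, -dplyr::any_of("accepted")),
                   paths$features)
  readr::write_csv(hits, paths$hits)
  readr::write_csv(tibble::as_tibble(identifications), paths$identifications)
  jsonlite::write_json(
    list(tensors = tibble::as_tibble(identifications), hits = hits),
    paths$identifications_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(metrics, paths$metrics, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  write_run_config(cfg, paths$config)

  invisible(list(identifications = identifications, hits = hits,
                 matches = matches, metrics = metrics, paths = paths,
                 config = cfg))
}

# deterministic stratified split preserving the label ratio
stratified_label_split <- function(label, fraction, seed) {
  old <- get0(".Random.seed", globalenv())
  on.exit(restore_rng(old))
  set.seed(seed)
  train_idx <- integer(0)
  for (lv in unique(label)) {
    idx <- which(label == lv)
    train_idx <- c(train_idx, sample(idx, round(fraction * length(idx))))
  }
  train_idx <- sort(train_idx)
  list(train_idx = train_idx,
       test_idx = setdiff(seq_along(label), train_idx))
}
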