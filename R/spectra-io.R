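#' Construct a spectra table
#'
#' The package represents MS/MS spectra as a tibble with one row per
#' spectrum and a `peaks` list-column, each element a tibble with `mz`
#' (Da) and `intensity` columns. All downstream verbs
#' ([normalize_spectra()], [cnl_features()], [search_library()]) take and
#' return this shape, so calls chain with the pipe.
#'
#' @param spectrum_id character vector of unique spectrum identifiers.
#' @param precursor_mz numeric vector of precursor m/z values (Da, > 0).
#' @param peaks list of data frames, each with columns `mz` and
#'   `intensity`. Peaks are sorted ascending by m/z and peaks more than
#'   0.5 Da above the precursor are dropped (isotope/noise guard).
#' @param polarity `"positive"` or `"negative"`, recycled.
#' @param adduct,compound_id,monoisotopic_mass optional per-spectrum
#'   metadata (adduct string, InChIKey, neutral monoisotopic mass in Da).
#'
#' @return A tibble of class `nta_spectra`.
#' @export
#' @examples
#' spectra_tbl("s1", 300, list(data.frame(mz = c(100, 250), intensity = c(5, 10))))
spectra_tbl <- function(spectrum_id, precursor_mz, peaks,
                        polarity = "positive", adduct = NA_character_,
                        compound_id = NA_character_,
                        monoisotopic_mass = NA_real_) {
  stopifnot(length(spectrum_id) == length(precursor_mz),
            length(peaks) == length(spectrum_id))
  if (any(!is.finite(precursor_mz) | precursor_mz <= 0)) {
    stop("`precursor_mz` must be finite and > 0 for every spectrum.", call. = FALSE)
  }
  peaks <- purrr::map2(peaks, precursor_mz, clean_peaks)
  if (!all(polarity %in% c("positive", "negative"))) {
    stop("`polarity` must be 'positive' or 'negative'.", call. = FALSE)
  }
  out <- tibble::tibble(
    spectrum_id = as.character(spectrum_id),
    precursor_mz = as.numeric(precursor_mz),
    polarity = rep_len(as.character(polarity), length(spectrum_id)),
    adduct = rep_len(as.character(adduct), length(spectrum_id)),
    compound_id = rep_len(as.character(compound_id), length(spectrum_id)),
    monoisotopic_mass = rep_len(as.numeric(monoisotopic_mass), length(spectrum_id)),
    peaks = peaks
  )
  class(out) <- c("nta_spectra", class(out))
  out
}

# sort ascending, drop peaks above precursor + 0.5 Da, drop NA rows
clean_peaks <- function(pk, precursor_mz) {
  pk <- tibble::as_tibble(pk)
  stopifnot(all(c("mz", "intensity") %in% names(pk)))
  pk <- pk[is.finite(pk$mz) & is.finite(pk$intensity) & pk$mz > 0 &
             pk$intensity >= 0, c("mz", "intensity")]
  pk <- pk[pk$mz <= precursor_mz + 0.5, ]
  pk[order(pk$mz), ]
}

#' Normalize spectra to base peak 1
#'
#' Divides every peak intensity by the spectrum's maximum intensity so the
#' base peak is exactly 1. Peak order is preserved; the operation is
#' idempotent.
#'
#' @param spectra an `nta_spectra` tibble (see [spectra_tbl()]).
#' @return The same tibble with normalized `peaks`.
#' @export
normalize_spectra <- function(spectra) {
  stopifnot(is.data.frame(spectra), "peaks" %in% names(spectra))
  spectra$peaks <- purrr::map2(spectra$peaks, spectra$spectrum_id, function(pk, id) {
    if (nrow(pk) == 0L || max(pk$intensity) <= 0) {
      stop("Degenerate spectrum '", id,
           "': no peak with positive intensity to normalize.", call. = FALSE)
    }
    pk$intensity <- pk$intensity / max(pk$intensity)
    pk
  })
  spectra
}

#' Read MS/MS spectra from MSP or MGF files
#'
#' Dispatches on the file extension: `.msp` is parsed as the NIST text
#' dialect (`Name:` / `PrecursorMZ:` / `Num Peaks:` records), `.mgf` as
#' `BEGIN IONS` blocks. Both `PrecursorMZ` and `PRECURSORMZ` spellings are
#' accepted, and peak lines may be whitespace- or tab-separated. Records
#' without a precursor m/z are skipped with a warning giving the count.
#'
#' @param path path to an existing `.msp` or `.mgf` file.
#' @return An `nta_spectra` tibble, one row per parsed record.
#' @export
read_msp <- function(path) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  lines <- readLines(path, warn = FALSE)
  recs <- switch(ext,
    mgf = parse_mgf_blocks(lines, path),
    parse_msp_blocks(lines, path)
  )
  skipped <- sum(vapply(recs, function(r) is.na(r$precursor_mz), logical(1)))
  if (skipped > 0L) {
    warning(skipped, " record(s) without a precursor m/z were skipped in ",
            basename(path), call. = FALSE)
    recs <- recs[vapply(recs, function(r) !is.na(r$precursor_mz), logical(1))]
  }
  if (length(recs) == 0L) return(empty_spectra())
  spectra_tbl(
    spectrum_id = vapply(recs, `[[`, character(1), "id"),
    precursor_mz = vapply(recs, `[[`, numeric(1), "precursor_mz"),
    peaks = purrr::map(recs, "peaks"),
    polarity = vapply(recs, `[[`, character(1), "polarity"),
    adduct = vapply(recs, `[[`, character(1), "adduct"),
    compound_id = vapply(recs, `[[`, character(1), "compound_id"),
    monoisotopic_mass = vapply(recs, `[[`, numeric(1), "monoisotopic_mass")
  )
}

empty_spectra <- function() {
  spectra_tbl(character(0), numeric(0), list())
}

parse_peak_line <- function(line, path, lineno) {
  parts <- strsplit(trimws(line), "[ \t;]+")[[1]]
  vals <- suppressWarnings(as.numeric(parts[1:2]))
  if (length(parts) < 2L || anyNA(vals)) {
    stop("Cannot parse ", basename(path), ": bad peak line ", lineno,
         ": '", line, "'", call. = FALSE)
  }
  vals
}

is_peak_line <- function(line) grepl("^\\s*[0-9]", line)

parse_msp_blocks <- function(lines, path) {
  recs <- list()
  cur <- NULL
  n_rec <- 0L
  flush <- function(cur) {
    if (is.null(cur)) return(NULL)
    cur$peaks <- if (length(cur$mz)) {
      tibble::tibble(mz = cur$mz, intensity = cur$int)
    } else {
      tibble::tibble(mz = numeric(0), intensity = numeric(0))
    }
    cur
  }
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(trimws(line))) next
    if (grepl("^name\\s*:", line, ignore.case = TRUE)) {
      if (!is.null(cur)) recs[[length(recs) + 1L]] <- flush(cur)
      n_rec <- n_rec + 1L
      cur <- list(id = trimws(sub("^[^:]*:", "", line)),
                  precursor_mz = NA_real_, polarity = "positive",
                  adduct = NA_character_, compound_id = NA_character_,
                  monoisotopic_mass = NA_real_,
                  mz = numeric(0), int = numeric(0))
      if (!nzchar(cur$id)) cur$id <- paste0("spectrum_", n_rec)
    } else if (is.null(cur)) {
      stop("Cannot parse ", basename(path), ": line ", i,
           " precedes any 'Name:' record: '", line, "'", call. = FALSE)
    } else if (grepl(":", line, fixed = TRUE) && !is_peak_line(line)) {
      key <- tolower(trimws(sub(":.*$", "", line)))
      val <- trimws(sub("^[^:]*:", "", line))
      if (key %in% c("precursormz", "precursor_mz")) {
        cur$precursor_mz <- suppressWarnings(as.numeric(val))
      } else if (key == "ionmode" || key == "ion_mode") {
        cur$polarity <- if (grepl("^n", tolower(val))) "negative" else "positive"
      } else if (key %in% c("precursortype", "adduct")) {
        cur$adduct <- val
      } else if (key == "inchikey") {
        cur$compound_id <- val
      } else if (key %in% c("exactmass", "monoisotopic_mass", "mw")) {
        cur$monoisotopic_mass <- suppressWarnings(as.numeric(val))
      }
      # "Num Peaks:" and unknown keys: peak count is implied by the lines
    } else if (is_peak_line(line)) {
      vals <- parse_peak_line(line, path, i)
      cur$mz <- c(cur$mz, vals[1])
      cur$int <- c(cur$int, vals[2])
    } else {
      stop("Cannot parse ", basename(path), ": line ", i, ": '", line, "'",
           call. = FALSE)
    }
  }
  if (!is.null(cur)) recs[[length(recs) + 1L]] <- flush(cur)
  recs
}

parse_mgf_blocks <- function(lines, path) {
  recs <- list()
  cur <- NULL
  n_rec <- 0L
  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (!nzchar(line) || grepl("^#", line)) next
    if (toupper(line) == "BEGIN IONS") {
      n_rec <- n_rec + 1L
      cur <- list(id = paste0("spectrum_", n_rec),
                  precursor_mz = NA_real_, polarity = "positive",
                  adduct = NA_character_, compound_id = NA_character_,
                  monoisotopic_mass = NA_real_,
                  mz = numeric(0), int = numeric(0))
    } else if (toupper(line) == "END IONS") {
      if (is.null(cur)) {
        stop("Cannot parse ", basename(path), ": line ", i,
             ": END IONS without BEGIN IONS", call. = FALSE)
      }
      cur$peaks <- tibble::tibble(mz = cur$mz, intensity = cur$int)
      recs[[length(recs) + 1L]] <- cur
      cur <- NULL
    } else if (is.null(cur)) {
      stop("Cannot parse ", basename(path), ": line ", i,
           " outside BEGIN IONS block: '", line, "'", call. = FALSE)
    } else if (grepl("=", line, fixed = TRUE)) {
      key <- toupper(sub("=.*$", "", line))
      val <- sub("^[^=]*=", "", line)
      if (key == "PEPMASS") {
        cur$precursor_mz <- suppressWarnings(as.numeric(strsplit(val, "\\s+")[[1]][1]))
      } else if (key == "TITLE") {
        cur$id <- val
      } else if (key == "CHARGE") {
        cur$polarity <- if (grepl("-", val, fixed = TRUE)) "negative" else "positive"
      } else if (key == "INCHIKEY") {
        cur$compound_id <- val
      }
    } else if (is_peak_line(line)) {
      vals <- parse_peak_line(line, path, i)
      cur$mz <- c(cur$mz, vals[1])
      cur$int <- c(cur$int, vals[2])
    } else {
      stop("Cannot parse ", basename(path), ": line ", i, ": '", line, "'",
           call. = FALSE)
    }
  }
  recs
}

#' Write spectra to an MSP file
#'
#' Inverse of [read_msp()] for the MSP dialect; round-trips precursor m/z,
#' peak lists, polarity, adduct and compound metadata.
#'
#' @param spectra an `nta_spectra` tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_msp <- function(spectra, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(spectra))) {
    writeLines(c(
      paste0("Name: ", spectra$spectrum_id[i]),
      paste0("PrecursorMZ: ", format(spectra$precursor_mz[i], digits = 12)),
      if (!is.na(spectra$adduct[i])) paste0("PrecursorType: ", spectra$adduct[i]),
      if (!is.na(spectra$compound_id[i])) paste0("InChIKey: ", spectra$compound_id[i]),
      if (!is.na(spectra$monoisotopic_mass[i]))
        paste0("ExactMass: ", format(spectra$monoisotopic_mass[i], digits = 12)),
      paste0("IonMode: ", if (spectra$polarity[i] == "negative") "Negative" else "Positive"),
      paste0("Num Peaks: ", nrow(spectra$peaks[[i]]))
    ), con)
    pk <- spectra$peaks[[i]]
    if (nrow(pk)) {
      writeLines(paste(format(pk$mz, digits = 12, trim = TRUE),
                       format(pk$intensity, digits = 12, trim = TRUE)), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Read a compound table
#'
#' Reads a CSV of compound records with mandatory columns `inchikey`,
#' `smiles` and `monoisotopic_mass` and an optional `rti` column holding
#' true retention-time indices on the harmonized scale. Duplicate
#' InChIKeys collapse to their first occurrence with a warning.
#'
#' @param path path to a UTF-8, comma-separated CSV file.
#' @return A tibble with columns `inchikey`, `smiles`,
#'   `monoisotopic_mass`, `rti`.
#' @export
read_compound_table <- function(path) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  names(tab) <- tolower(names(tab))
  needed <- c("inchikey", "smiles", "monoisotopic_mass")
  missing <- setdiff(needed, names(tab))
  if (length(missing)) {
    stop("Compound table ", basename(path), " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(tab$monoisotopic_mass)) {
    stop("Column 'monoisotopic_mass' in ", basename(path),
         " is not numeric.", call. = FALSE)
  }
  if (!"rti" %in% names(tab)) tab$rti <- NA_real_
  if (!is.numeric(tab$rti)) stop("Column 'rti' is not numeric.", call. = FALSE)
  dup <- duplicated(tab$inchikey)
  if (any(dup)) {
    warning(sum(dup), " duplicate InChIKey(s) collapsed to first occurrence.",
            call. = FALSE)
    tab <- tab[!dup, ]
  }
  tibble::as_tibble(tab[, c("inchikey", "smiles", "monoisotopic_mass", "rti")])
}
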