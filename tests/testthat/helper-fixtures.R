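# one-row spectra table from bare vectors
make_spec <- function(id, precursor, mz, intensity = rep(1, length(mz)), ...) {
  spectra_tbl(id, precursor,
              list(data.frame(mz = mz, intensity = intensity)), ...)
}

write_tmp <- function(lines, ext = ".msp") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# worlds are expensive; share them across test files by key
.world_cache <- new.env(parent = emptyenv())
cached_world <- function(key, ...) {
  if (is.null(.world_cache[[key]])) .world_cache[[key]] <- generate_world(...)
  .world_cache[[key]]
}

zero_noise <- list(mz_sd = 0, intensity_sd = 0, rti_sd = 0, dropout = 0)

six_features <- c("RefMatchFragRatio", "MS1Error", "MS2ErrorStd",
                  "FinalScoreRatio", "monoisotopic_mass", "rti_error")
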