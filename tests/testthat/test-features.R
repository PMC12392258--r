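test_that("neutral losses are precursor-minus-fragment, non-negative, sorted", {
  sp <- make_spec("s", 300, mz = c(100, 250))
  nl <- neutral_losses(sp)
  expect_equal(nl$loss, c(50, 200))

  at_prec <- make_spec("p", 300, mz = c(100, 300))
  expect_true(0 %in% neutral_losses(at_prec)$loss)

  set.seed(7)
  for (i in 1:20) {
    n <- sample(1:40, 1)
    sp <- make_spec("r", 500, mz = sort(runif(n, 10, 500)))
    nl <- neutral_losses(sp)
    expect_lte(nrow(nl), n)
    expect_true(all(nl$loss >= 0))
    expect_false(is.unsorted(nl$loss))
  }
})

test_that("CNL indicators mark MOI bins within tolerance", {
  moi <- moi_list(c(50, 120, 200), tolerance = 0.01)
  sp <- make_spec("s", 300, mz = c(100, 250), compound_id = "X",
                  monoisotopic_mass = 299)
  f <- cnl_features(sp, moi, drop_below_min = FALSE)
  expect_equal(as.integer(f$cnl[1, ]), c(1L, 0L, 1L))
  expect_equal(f$monoisotopic_mass, 299)

  # boundary hit at 50.005 sets the 50.0 bin but fails the 2-MOI minimum
  near <- make_spec("b", 300, mz = 300 - 50.005)
  expect_warning(f2 <- cnl_features(near, moi), "2-MOI minimum")
  expect_equal(nrow(f2), 0L)
  f2b <- cnl_features(near, moi, drop_below_min = FALSE)
  expect_equal(as.integer(f2b$cnl[1, ]), c(1L, 0L, 0L))

  # positive-mode fallback monoisotopic mass: precursor minus proton
  no_mass <- make_spec("m", 300, mz = c(100, 250))
  fm <- cnl_features(no_mass, moi, drop_below_min = FALSE)
  expect_equal(fm$monoisotopic_mass, 300 - 1.00728)
})

test_that("CNL indicators equal a brute-force interval test on random input", {
  set.seed(11)
  for (rep in 1:10) {
    masses <- sort(runif(15, 10, 200))
    masses <- masses[c(TRUE, diff(masses) > 0.05)]
    moi <- moi_list(masses, tolerance = 0.02)
    prec <- 300
    mz <- sort(runif(sample(2:25, 1), 50, 295))
    sp <- make_spec("r", prec, mz = mz)
    got <- cnl_features(sp, moi, drop_below_min = FALSE)$cnl[1, ]
    losses <- prec - mz
    want <- vapply(moi$masses, function(m) any(abs(losses - m) <= 0.02),
                   logical(1))
    expect_equal(as.logical(got), want)
  }
})

test_that("CNL features ignore intensity rescaling", {
  moi <- moi_list(c(50, 120, 200), tolerance = 0.01)
  a <- make_spec("a", 300, mz = c(100, 250), intensity = c(1, 1))
  b <- make_spec("a", 300, mz = c(100, 250), intensity = c(500, 9))
  expect_identical(cnl_features(a, moi, drop_below_min = FALSE)$cnl,
                   cnl_features(b, moi, drop_below_min = FALSE)$cnl)
})

test_that("MOI lists enforce ascending, non-overlapping bins", {
  expect_error(moi_list(c(50, 50.015), tolerance = 0.01), "overlap")
  expect_s3_class(moi_list(c(50, 50.03), tolerance = 0.01), "moi_list")
  path <- tempfile(fileext = ".csv")
  write_moi_list(moi_list(c(18.011, 44.998)), path)
  back <- read_moi_list(path)
  expect_equal(back$masses, c(18.011, 44.998))
})

test_that("MOI selection retains bins by document frequency", {
  # every spectrum loses water; one loses a rare 77 Da fragment
  sp <- dplyr::bind_rows(lapply(1:10, function(i) {
    mz <- c(300 - 18.011, if (i == 1) 300 - 77.0)
    make_spec(paste0("s", i), 300, mz = mz)
  }))
  moi_all <- select_mois(sp, min_frequency = 0.05, tolerance = 0.01)
  expect_true(any(abs(moi_all$masses - 18.011) < 0.01))
  expect_true(any(abs(moi_all$masses - 77.0) < 0.01))
  moi_half <- select_mois(sp, min_frequency = 0.5, tolerance = 0.01)
  expect_true(any(abs(moi_half$masses - 18.011) < 0.01))
  expect_false(any(abs(moi_half$masses - 77.0) < 0.01))
  expect_error(select_mois(sp[0, ]), "empty")
})

test_that("MOI selection matches brute-force frequencies and spacing invariant", {
  w <- cached_world("moi", n_compounds = 30, spectra_per_compound = 3,
                    noise = zero_noise, seed = 5)
  tol <- 0.01
  moi <- select_mois(w$spectra, min_frequency = 0.2, tolerance = tol)
  expect_true(all(diff(moi$masses) > 2 * tol))
  # oracle: per vocabulary mass, count spectra with a loss within tol
  nl <- neutral_losses(w$spectra)
  for (m in w$moi$masses) {
    freq <- length(unique(nl$spectrum_id[abs(nl$loss - m) <= tol])) /
      nrow(w$spectra)
    hit <- any(abs(moi$masses - m) <= tol)
    if (freq >= 0.2) expect_true(hit) else expect_false(hit)
  }
})

test_that("hash fingerprints are deterministic and reject bad structures", {
  be <- fp_backend_hash()
  expect_identical(fingerprint("CCO", be), fingerprint("CCO", be))
  expect_equal(length(fingerprint("CCO", be)), 790L)
  expect_false(identical(fingerprint("CCO", be),
                         fingerprint("c1ccccc1O", be)))
  expect_error(fingerprint("not_a_smiles", be), "Cannot parse")
  expect_error(fingerprint("C(C(", be), "unbalanced")
})

test_that("ChemmineR backend yields fixed-length atom-pair keys", {
  be <- fp_backend_chemminer(1024L)
  fp1 <- fingerprint("CCO", be)
  expect_equal(length(fp1), 1024L)
  expect_identical(fp1, fingerprint("CCO", be))
  expect_false(identical(fp1, fingerprint("c1ccccc1O", be)))
})

test_that("leverage matches the closed form and the trace identity", {
  ad <- suppressWarnings(fit_ad(diag(2)))
  expect_equal(leverage(ad, c(1, 0)), 1.0)
  expect_equal(leverage(ad, c(0, 0)), 0.0)
  expect_error(leverage(ad, c(1, 0, 0)), "expects")

  set.seed(9)
  for (rep in 1:20) {
    X <- matrix(rnorm(50 * 5), 50, 5)
    ad <- fit_ad(X)
    expect_equal(sum(leverage(ad, X)), 5, tolerance = 1e-8)
    expect_true(all(ad$training_leverage >= 0 & ad$training_leverage <= 1))
  }
})

test_that("AD threshold is the smallest leverage covering 95% of training", {
  set.seed(13)
  X <- matrix(rnorm(100 * 4), 100, 4)
  ad <- fit_ad(X)
  h <- ad$training_leverage
  expect_true(ad$threshold %in% h)
  expect_gte(mean(h <= ad$threshold), 0.95)
  smaller <- max(h[h < ad$threshold])
  expect_lt(mean(h <= smaller), 0.95)
  expect_identical(in_domain(ad, X), leverage(ad, X) <= ad$threshold)

  # equal leverages: threshold equals the common value
  ad_eq <- suppressWarnings(fit_ad(diag(4)))
  expect_equal(ad_eq$threshold, 1)

  expect_error(fit_ad(matrix(numeric(0), 0, 2)), "empty")
  expect_warning(fit_ad(matrix(rnorm(6), 2, 3)), "n <= p")
})

test_that("singular designs fall back to a pseudo-inverse", {
  X <- cbind(1:10, 1:10)  # rank 1
  ad <- fit_ad(X)
  expect_true(all(is.finite(ad$training_leverage)))
  expect_equal(sum(ad$training_leverage), 1, tolerance = 1e-8)  # rank, not p
})
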