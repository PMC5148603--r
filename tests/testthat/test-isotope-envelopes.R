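test_that("peptide compositions follow the residue table plus one water", {
  expect_equal(compositionFromSequence("G"),
               c(C = 2L, H = 5L, N = 1L, O = 2L, S = 0L))
  expect_equal(compositionFromSequence("GG"),
               c(C = 4L, H = 8L, N = 2L, O = 3L, S = 0L))
  ## composition is order-invariant
  expect_equal(compositionFromSequence("AGP"),
               compositionFromSequence("APG"))
  expect_error(compositionFromSequence("AGX"), "position 3")
  expect_error(compositionFromSequence(""), "nonempty")
})

test_that("average peptide masses agree with an independent calculator", {
  ## seqinr::pmw computes the average molecular weight of a peptide
  for (seq in c("GLSDGEWQLVLNVWGK", "ACDEFGHIKLMNPQRSTVWY", "PPGF")) {
    mine <- averageMass(compositionFromSequence(seq))
    ref <- seqinr::pmw(strsplit(seq, "")[[1]])
    expect_lt(abs(mine - ref), 0.5)
  }
})

test_that("averagine compositions scale to the target mass", {
  unit <- averagineComposition(111.1254)
  expect_equal(unname(unit[c("C", "N", "O", "S")]), c(5L, 1L, 1L, 0L))
  expect_lt(abs(averageMass(unit) - 111.1254), 111.1254)
  big <- averagineComposition(3800)
  expect_lt(abs(averageMass(big) - 3800), 111.1254)
  expect_true(all(big >= 0))
  expect_error(averagineComposition(0), "positive")
  expect_error(averagineComposition(-5), "positive")
})

test_that("single-element envelopes match the isotope table", {
  env <- peaks(naturalEnvelope(c(C = 1)))
  expect_equal(env$mass, c(12.0000000, 13.0033548), tolerance = 1e-7)
  expect_equal(env$abundance, c(0.9893, 0.0107), tolerance = 1e-9)
  water <- peaks(naturalEnvelope(c(H = 2, O = 1)))
  ## monoisotopic abundance = 0.999885^2 * 0.99757
  expect_equal(water$abundance[1], 0.999885^2 * 0.99757,
               tolerance = 1e-6)
})

test_that("natural envelopes agree with brute-force enumeration", {
  set.seed(7)
  comps <- list(c(C = 3, H = 4, O = 2), c(C = 2, H = 2, N = 2, O = 1),
                c(C = 1, H = 3, N = 1, O = 1, S = 1),
                c(C = 5, H = 5), c(O = 3, S = 2))
  for (comp in comps) {
    mine <- peaks(naturalEnvelope(comp, truncation = 1e-12))
    oracle <- bruteForceEnvelope(comp)
    oracle <- oracle[oracle$abundance >= 1e-12 * max(oracle$abundance), ]
    expect_equal(nrow(mine), nrow(oracle))
    expect_equal(mine$abundance, oracle$abundance / sum(oracle$abundance),
                 tolerance = 1e-9)
    expect_equal(mine$mass, oracle$mass, tolerance = 1e-7)
  }
})

test_that("natural envelopes are normalized and degenerate inputs flagged", {
  for (m in c(500, 1500, 3800)) {
    env <- naturalEnvelope(averagineComposition(m))
    expect_equal(sum(peaks(env)$abundance), 1, tolerance = 1e-9)
  }
  degenerate <- naturalEnvelope(c(C = 0))
  expect_equal(peaks(degenerate), data.frame(mass = 0, abundance = 1))
  expect_true("degenerate" %in% degenerate@flags)
  expect_error(naturalEnvelope(c(C = 10), truncation = 0), "truncation")
  expect_error(naturalEnvelope(c(Xx = 1)), "unknown element")
})

test_that("exchangeable amide counting skips the N-terminus and prolines", {
  expect_equal(nExchangeableAmides("AGPM"), 2L)
  expect_equal(nExchangeableAmides("AA"), 1L)
  expect_equal(nExchangeableAmides("AP"), 0L)
  ## N-terminal proline is excluded anyway, so it costs nothing extra
  expect_equal(nExchangeableAmides("PAA"), 2L)
})

test_that("deuteration convolution is binomial with exact centroid shift", {
  single <- IsotopeEnvelope(1000, 1, normalized = TRUE)
  out <- peaks(applyDeuteration(single, 2, 0.5))
  expect_equal(out$abundance, c(0.25, 0.5, 0.25), tolerance = 1e-12)
  expect_equal(out$mass, 1000 + 0:2 * 1.00628, tolerance = 1e-9)

  env <- naturalEnvelope(averagineComposition(3800))
  shifted <- applyDeuteration(env, 31, 0.7)
  expect_equal(centroidMass(shifted) - centroidMass(env),
               31 * 0.7 * 1.00628, tolerance = 1e-6)
  ## identities
  expect_equal(peaks(applyDeuteration(env, 31, 0)), peaks(env),
               tolerance = 1e-12)
  expect_equal(peaks(applyDeuteration(env, 0, 0.5)), peaks(env),
               tolerance = 1e-12)
  expect_error(applyDeuteration(env, 31, 1.2), "pIncorp")
  expect_error(applyDeuteration(env, -1, 0.5), "nAmides")
})

test_that("mixtures preserve normalization and centroid linearity", {
  nat <- naturalEnvelope(averagineComposition(3800))
  f <- applyDeuteration(nat, 31, 0.25)
  u <- applyDeuteration(nat, 31, 0.70)
  expect_identical(peaks(mixEnvelopes(f, u, 0)), peaks(f))
  expect_identical(peaks(mixEnvelopes(f, u, 1)), peaks(u))
  set.seed(11)
  for (w in runif(8)) {
    mix <- mixEnvelopes(f, u, w)
    expect_equal(sum(peaks(mix)$abundance), 1, tolerance = 1e-9)
    expect_equal(centroidMass(mix),
                 (1 - w) * centroidMass(f) + w * centroidMass(u),
                 tolerance = 1e-9)
  }
  expect_error(mixEnvelopes(f, u, 1.5), "wUnfolded")
})

test_that("centroid mass is the abundance-weighted mean", {
  expect_equal(centroidMass(IsotopeEnvelope(1000, 1)), 1000)
  expect_equal(centroidMass(IsotopeEnvelope(c(10, 20), c(0.5, 0.5))), 15)
  expect_error(centroidMass(IsotopeEnvelope(numeric(), numeric())),
               "empty")
})

test_that("m/z conversion uses the proton mass and round-trips", {
  env <- IsotopeEnvelope(c(1000, 1001), c(0.6, 0.4), normalized = TRUE)
  mz1 <- toMz(env, 1)
  expect_equal(mz1$mz[1], 1001.00728)
  mz2 <- toMz(env, 2)
  expect_equal(mz2$mz[1], 501.00728)
  back <- fromMz(mz2, 2, normalized = TRUE)
  expect_equal(peaks(back)$mass, peaks(env)$mass, tolerance = 1e-6)
  expect_error(toMz(env, 0), "charge")
  expect_error(fromMz(mz1, 0.5), "charge")
})

test_that("envelope serialization round-trips through delimited text", {
  env <- naturalEnvelope(compositionFromSequence("PEPTIDE"))
  path <- withr::local_tempfile(fileext = ".csv")
  writeEnvelope(env, path)
  header <- readLines(path, n = 1)
  expect_equal(header, "mass_da,abundance")
  back <- readEnvelope(path, normalized = TRUE)
  expect_equal(peaks(back), peaks(env), tolerance = 1e-12)
})

test_that("envelope validity rejects malformed objects", {
  expect_error(new("IsotopeEnvelope", mass = c(1, 2),
                   abundance = c(-0.1, 1.1), normalized = FALSE,
                   flags = character()),
               "nonnegative")
  expect_error(new("IsotopeEnvelope", mass = c(2, 1),
                   abundance = c(0.5, 0.5), normalized = FALSE,
                   flags = character()),
               "increasing")
  expect_error(new("IsotopeEnvelope", mass = c(1, 2),
                   abundance = c(0.5, 0.6), normalized = TRUE,
                   flags = character()),
               "sum to 1")
  ## the constructor sorts peaks
  env <- IsotopeEnvelope(c(2, 1), c(0.25, 0.75), normalized = TRUE)
  expect_equal(peaks(env)$mass, c(1, 2))
})

test_that("peptide specs validate coordinates, sequence and amides", {
  p <- PeptideSpec("LPL", 131, 165, nExchangeable = 31, massDa = 3800)
  expect_equal(p@end - p@start + 1L, 35L)
  expect_error(PeptideSpec("X", 10, 5), "start")
  expect_error(PeptideSpec("X", 1, 3, sequence = "AA"), "length")
  expect_error(PeptideSpec("X", 1, 3, sequence = "AAA",
                           nExchangeable = 5), "nExchangeable")
  ## derived from sequence when not supplied
  expect_equal(PeptideSpec("X", 1, 4, sequence = "AGPM")@nExchangeable,
               2L)
})
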