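mkUptake <- function(peptide, start, end, time_s, uptake, sd = 0.05,
                     rel = uptake / 20, n = 3) {
  data.frame(peptide = peptide, start = start, end = end,
             time_s = time_s, uptake_da = uptake, rel_uptake = rel,
             sd = sd, n = n)
}

test_that("relative uptake is a guarded ratio", {
  expect_equal(relativeUptake(20, 20), 1.0)
  expect_equal(relativeUptake(0, 20), 0.0)
  expect_equal(relativeUptake(5, 20), 0.25)
  over <- relativeUptake(21, 20)
  expect_true(isTRUE(attr(over, "exceeds_control")))
  expect_equal(as.numeric(over), 1.05)
  expect_error(relativeUptake(5, 0), "positive")
})

test_that("heat maps project peptide values onto residues", {
  recs <- rbind(mkUptake("a", 1, 10, 10, 10, rel = 0.5))
  m <- heatmapMatrix(recs, 20)
  expect_equal(unname(m[1:10, 1]), rep(0.5, 10))
  expect_true(all(is.na(m[11:20, 1])))
  ## overlapping peptides average residue-wise
  recs2 <- rbind(mkUptake("a", 1, 10, 10, 4, rel = 0.2),
                 mkUptake("b", 5, 20, 10, 12, rel = 0.6))
  m2 <- heatmapMatrix(recs2, 40)
  expect_equal(unname(m2[5:10, 1]), rep(0.4, 6))
  expect_equal(unname(m2[1:4, 1]), rep(0.2, 4))
  expect_equal(unname(m2[11:20, 1]), rep(0.6, 10))
  expect_true(all(is.na(m2[21:40, 1])))
  ## shortest-peptide priority option
  m3 <- heatmapMatrix(recs2, 40, rule = "shortest")
  expect_equal(unname(m3[5:10, 1]), rep(0.2, 6))
  ## provenance names the covering peptides
  expect_setequal(attr(m2, "provenance")[[7]], c("a", "b"))
  ## residue values stay within the contributing peptide range
  set.seed(5)
  recs4 <- do.call(rbind, lapply(1:10, function(i) {
    s <- sample(1:30, 1)
    mkUptake(paste0("p", i), s, s + sample(5:15, 1), 10,
             runif(1, 0, 20), rel = runif(1))
  }))
  recs4$end <- pmin(recs4$end, 40)
  m4 <- heatmapMatrix(recs4, 40)
  for (res in 1:40) {
    cov <- recs4[recs4$start <= res & recs4$end >= res, ]
    if (!nrow(cov)) expect_true(is.na(m4[res, 1]))
    else {
      expect_gte(m4[res, 1], min(cov$rel_uptake) - 1e-12)
      expect_lte(m4[res, 1], max(cov$rel_uptake) + 1e-12)
    }
  }
  expect_error(heatmapMatrix(mkUptake("a", 0, 5, 10, 1), 20),
               "coordinates")
  empty <- heatmapMatrix(mkUptake("a", 1, 5, 10, 1)[0, ], 20)
  expect_true(all(is.na(empty)))
})

test_that("the significance threshold is the largest replicate SD", {
  expect_equal(significanceThreshold(c(0.05, 0.12, 0.08)), 0.12)
  expect_equal(significanceThreshold(0.3), 0.3)
  expect_equal(significanceThreshold(c(0, 0, 0)), 0)
  expect_error(significanceThreshold(numeric()), "at least one")
})

test_that("butterfly differences are antisymmetric and gated by max SD", {
  ref <- rbind(mkUptake("a", 1, 10, 10, 5), mkUptake("b", 11, 20, 10, 8))
  var <- rbind(mkUptake("a", 1, 10, 10, 5.3),
               mkUptake("b", 11, 20, 10, 7.99))
  d <- butterflyDifferences(ref, var)
  expect_equal(attr(d, "threshold"), 0.05)
  expect_equal(d$diff_da, c(0.3, -0.01), tolerance = 1e-12)
  expect_equal(d$significant, c(TRUE, FALSE))
  ## identity: no differences, nothing significant
  self <- butterflyDifferences(ref, ref)
  expect_true(all(self$diff_da == 0))
  expect_false(any(self$significant))
  ## antisymmetry under swapping reference and variant
  swapped <- butterflyDifferences(var, ref)
  expect_equal(swapped$diff_da, -d$diff_da)
  ## single-peptide inputs and mismatch logging
  one <- butterflyDifferences(mkUptake("a", 1, 10, 10, 5),
                              rbind(mkUptake("a", 1, 10, 10, 6),
                                    mkUptake("c", 30, 40, 10, 6)))
  expect_equal(nrow(one), 1)
  expect_equal(attr(one, "dropped"), "c")
  expect_error(butterflyDifferences(mkUptake("a", 1, 10, 10, 5),
                                    mkUptake("z", 1, 10, 10, 5)),
               "shared")
})

test_that("bimodality bins are respected when present", {
  ref <- rbind(cbind(mkUptake("a", 1, 10, 10, 5), bin = "10-15"),
               cbind(mkUptake("a", 1, 10, 10, 7), bin = "15-20"))
  var <- rbind(cbind(mkUptake("a", 1, 10, 10, 5.5), bin = "10-15"),
               cbind(mkUptake("a", 1, 10, 10, 7.2), bin = "15-20"))
  d <- butterflyDifferences(ref, var)
  expect_equal(nrow(d), 2)
  expect_setequal(round(d$diff_da, 6), c(0.5, 0.2))
})

test_that("envelope variance matches the mixture closed form", {
  ## two Gaussians, sigma 1.5 Da, separation 10 Da, equal weights:
  ## variance = sigma^2 + w(1-w) d^2 = 2.25 + 25 = 27.25
  env <- gaussianSticks(c(100, 110), c(1.5, 1.5), c(1, 1),
                        spacing = 0.25, pad = 14)
  m <- ex1WidthMetric(list(env, env), c(10, 100))
  expect_equal(m$table$variance[1], 27.25, tolerance = 1e-6 * 27.25)
  ## and w(1-w) is maximal at one half
  vw <- function(w) {
    e <- gaussianSticks(c(100, 110), c(1.5, 1.5), c(1 - w, w),
                        spacing = 0.25, pad = 14)
    ex1WidthMetric(list(e, e), c(1, 2))$table$variance[1]
  }
  expect_equal(vw(0.5), 27.25, tolerance = 1e-6 * 27.25)
  expect_lt(vw(0.2), vw(0.5))
  expect_lt(vw(0.8), vw(0.5))
})

test_that("EX1 and EX2 series are classified by transient broadening", {
  pep <- PeptideSpec("X", 1, 20, nExchangeable = 18,
                     massDa = 20 * 111.1254)
  quiet <- noiseModel(cv = 0, baseline = 0, seed = 1)
  ex2 <- simulateContinuousLabeling(list(list(peptide = pep, pf = 20,
                                              kOpen = 0)),
                                    replicates = 1, noise = quiet)
  cls2 <- ex1WidthMetric(ex2, vapply(ex2, function(s) s@metadata$time_s,
                                     numeric(1)))
  expect_equal(cls2$classification, "EX2")
  ex1 <- simulateContinuousLabeling(list(list(peptide = pep, pf = 1e9,
                                              kOpen = 5e-3)),
                                    replicates = 1, noise = quiet)
  cls1 <- ex1WidthMetric(ex1, vapply(ex1, function(s) s@metadata$time_s,
                                     numeric(1)))
  expect_equal(cls1$classification, "EX1-containing")
  ## variance peaks at intermediate open fraction, then declines
  v <- cls1$table$variance
  expect_gt(v[2], v[1])
  expect_gt(v[2], v[3])
  ## single time point: metric only, no classification
  single <- ex1WidthMetric(ex1[1], 10)
  expect_true(is.na(single$classification))
})

test_that("sequence coverage is the union of covered residues", {
  peps <- list(PeptideSpec("P", 1, 10), PeptideSpec("P", 5, 20))
  expect_equal(sequenceCoverage(peps, 40), 50)
  expect_equal(sequenceCoverage(list(PeptideSpec("P", 1, 40)), 40), 100)
  expect_equal(sequenceCoverage(list(), 40), 0)
  ## order- and duplication-invariant
  expect_equal(sequenceCoverage(rev(c(peps, peps)), 40), 50)
  expect_error(sequenceCoverage(list(PeptideSpec("P", 30, 50)), 40),
               "outside")
})

test_that("uptake plots build without error", {
  recs <- rbind(mkUptake("a", 1, 10, 10, 5), mkUptake("a", 1, 10, 100, 9),
                mkUptake("b", 11, 20, 10, 3), mkUptake("b", 11, 20, 100, 6))
  d <- butterflyDifferences(recs, recs)
  expect_s3_class(plotButterfly(d), "ggplot")
  expect_s3_class(plotUptakeHeatmap(heatmapMatrix(recs, 20)), "ggplot")
})
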