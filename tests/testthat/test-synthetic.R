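test_that("stage presets reproduce the observed one-signal fractions", {
  pre <- stagePreset("spermatogonia-early-preleptotene")
  expect_equal(pre$pairingProb[["19"]], 24 / 26, tolerance = 1e-12)
  expect_equal(round(pre$pairingProb[["19"]], 4), 0.9231)
  expect_equal(round(pre$pairingProb[["1"]], 4), 0.6984)
  expect_equal(round(stagePreset("II")$pairingProb[["1"]], 4), 0.7544)
  for (st in c("pachytene", "round-spermatid")) {
    pp <- stagePreset(st)$pairingProb
    expect_true(all(pp[names(pp) != "Y"] == 1))
  }
  expect_true(is.na(pre$pairingProb[["Y"]]))
  expect_error(stagePreset("interphase"), "unknown stage")
})

test_that("the lymphocyte preset is uniform at the somatic baseline", {
  pre <- stagePreset("lymphocyte")
  expect_length(pre$chromosomes, 15)
  expect_true(all(pre$pairingProb == 0.1947))
  expect_true(all(stagePreset("lymphocyte",
    lymphocytePairing = 0.3)$pairingProb == 0.3))
  expect_error(stagePreset("lymphocyte", lymphocytePairing = 1.2))
})

test_that("the probe layout covers the karyotype with unique ids per round", {
  lay <- probeLayout("I")
  # every chromosome painted once per round across the seven regions
  for (rd in unique(lay$round))
    expect_setequal(lay$chromosome[lay$round == rd], chromosomeIds())
  # nine distinct chromosomes per region
  per_region <- tapply(lay$chromosome, lay$region,
                       function(x) length(unique(x)))
  expect_true(all(per_region == 9))
})

test_that("nucleus spec validation rejects bad parameters", {
  pre <- stagePreset("I")
  expect_error(nucleusSpec(pre, region = 1), "seed")
  expect_error(nucleusSpec(pre, region = 99, seed = 1), "region")
  expect_error(nucleusSpec(pre, region = 1, seed = 1,
                           semiaxesUm = c(2, -1, 2)), "positive")
  expect_error(nucleusSpec(pre, region = 1, seed = 1,
                           semiaxesUm = c(2, 2, 0.05)), "degenerate")
  expect_error(nucleusSpec(pre, region = 1, seed = 1,
                           assocDefault = 1.4), "\\[0, 1\\]")
  expect_error(nucleusSpec(pre, region = 1, seed = 1,
                           separationVox = 1), "at least 2")
})

test_that("territory targets exceeding nucleus capacity are an error", {
  pre <- mini_preset(p = 1, nvp_one = 30, nvp_two = 45)
  spec <- do.call(nucleusSpec,
                  c(list(pre, region = 1, seed = 5), small_geometry))
  expect_error(generateNucleus(spec), "capacity")
})

test_that("generation is deterministic for a fixed seed", {
  pre <- mini_preset()
  spec <- do.call(nucleusSpec,
                  c(list(pre, region = 1, seed = 99), small_geometry))
  a <- generateNucleus(spec)
  b <- generateNucleus(spec)
  expect_identical(a@stacks[["r1"]]@channels, b@stacks[["r1"]]@channels)
  expect_identical(a@groundTruth, b@groundTruth)
  spec2 <- do.call(nucleusSpec,
                   c(list(pre, region = 1, seed = 100), small_geometry))
  c_ <- generateNucleus(spec2)
  expect_false(identical(a@stacks[["r1"]]@channels,
                         c_@stacks[["r1"]]@channels))
})

test_that("forced pairing states give the promised connectivity structure", {
  for (p in c(0, 1)) {
    pre <- mini_preset(p = p)
    spec <- do.call(nucleusSpec,
                    c(list(pre, region = 1, seed = 300 + p),
                      small_geometry))
    rec <- generateNucleus(spec)
    gt <- rec@groundTruth
    for (ch in names(gt$territories)) {
      t <- gt$territories[[ch]]
      m <- truth_mask(rec, "territory", ch)
      ncomp <- max(canonical_labels(oracle_label(m, 26), m))
      if (p == 1) {
        expect_true(t$paired)
        expect_identical(ncomp, 1L)
      } else {
        expect_false(t$paired)
        expect_identical(ncomp, 2L)
        # copies share no voxel, and stay separate even corner-to-corner
        expect_length(intersect(t$copies[[1]], t$copies[[2]]), 0)
        expect_identical(max(canonical_labels(oracle_label(m, 6), m)), 2L)
      }
      # ground-truth state always agrees with the flood-fill check
      expect_identical(t$paired, ncomp == 1L)
    }
  }
})

test_that("territory voxels are inside the nucleus and truth matches spacing", {
  pre <- mini_preset(p = 0.5)
  spec <- do.call(nucleusSpec,
                  c(list(pre, region = 1, seed = 17), small_geometry))
  rec <- generateNucleus(spec)
  gt <- rec@groundTruth
  for (t in gt$territories)
    expect_true(all(t$union %in% gt$nucleus))
  expect_identical(unname(spacing(rec)), c(0.1, 0.1, 0.17))
})

test_that("noise- and blur-free stacks threshold exactly to the truth", {
  pre <- mini_preset(p = 0.5)
  spec <- do.call(nucleusSpec,
                  c(list(pre, region = 1, seed = 23, noiseSd = 0,
                         blurSigmaUm = 0), small_geometry))
  rec <- generateNucleus(spec)
  st <- rec@stacks[["r1"]]
  expect_identical(unname(getChannel(st, "DAPI") > 0),
                   unname(truth_mask(rec, "nucleus")))
  for (ch in c("1", "2", "3"))
    expect_identical(unname(getChannel(st, ch) > 0),
                     unname(truth_mask(rec, "territory", ch)))
})

test_that("population pairing frequencies follow the preset probability", {
  # 200 small nuclei, three chromosomes at p = 0.5: the realized paired
  # fraction should sit within 3 binomial SEs of 0.5
  pre <- mini_preset(p = 0.5)
  recs <- generatePopulation(pre, 200, seed = 1234,
                             semiaxesUm = small_geometry$semiaxesUm,
                             noiseSd = 0, blurSigmaUm = 0)
  paired <- unlist(lapply(recs, function(r)
    vapply(r@groundTruth$territories, `[[`, TRUE, "paired")))
  n <- length(paired)
  expect_identical(n, 600L)
  expect_lt(abs(mean(paired) - 0.5), 3 * sqrt(0.25 / n))
})

test_that("empty populations and single-copy chromosomes are handled", {
  pre <- mini_preset()
  expect_identical(generatePopulation(pre, 0, seed = 1), list())
  # region 7 of the germ-cell layout carries the single-copy Y
  gpre <- stagePreset("round-spermatid")
  spec <- nucleusSpec(gpre, region = 7, seed = 31,
                      semiaxesUm = c(2.2, 2, 1.6))
  rec <- generateNucleus(spec)
  y <- rec@groundTruth$territories[["Y"]]
  expect_true(is.na(y$paired))
  expect_length(y$copies, 1)
})

test_that("forced heterologous association shares voxels, exclusion does not", {
  pre <- mini_preset(p = 1)
  spec <- do.call(nucleusSpec, c(list(
    pre, region = 1, seed = 57, assocDefault = 0,
    assocPairs = data.frame(chr_a = "1", chr_b = "2", prob = 1)),
    small_geometry))
  rec <- generateNucleus(spec)
  av <- rec@groundTruth$associations
  key <- paste(av$chr_a, av$chr_b)
  expect_true(av$associated[key == "1 2"])
  expect_gt(av$shared_voxels[key == "1 2"], 0)
  expect_false(any(av$associated[key != "1 2"]))
  expect_true(all(av$shared_voxels[key != "1 2"] == 0))
})
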