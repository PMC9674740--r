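blob_mask <- function(d, ...) {
  m <- array(FALSE, d)
  for (r in list(...)) m[r[[1]], r[[2]], r[[3]]] <- TRUE
  m
}

test_that("pairing verdicts follow the one-versus-many component rule", {
  # one continuous 500-voxel signal -> paired
  m1 <- blob_mask(c(20, 20, 5), list(1:10, 1:10, 1:5))
  c1 <- classifyPairing(m1, chromosome = "3")
  expect_identical(c1$verdict, "paired")
  expect_identical(c1$n_components, 1L)
  # two separate entities sharing no voxel -> unpaired
  m2 <- blob_mask(c(30, 20, 5), list(1:8, 1:10, 1:5),
                  list(15:22, 1:10, 1:5))
  c2 <- classifyPairing(m2, chromosome = "3")
  expect_identical(c2$verdict, "unpaired")
  expect_identical(c2$n_components, 2L)
  expect_identical(c2$component_voxels, "400,400")
  # three components still collapse to the unpaired verdict
  m3 <- m2; m3[26:28, 1:10, 1:5] <- TRUE
  c3 <- classifyPairing(m3, chromosome = "3")
  expect_identical(c3$verdict, "unpaired")
  expect_identical(c3$n_components, 3L)
})

test_that("speckles below minSize are filtered before the verdict", {
  m <- blob_mask(c(20, 20, 5), list(1:10, 1:10, 1:5))
  m[18, 18, 1:3] <- TRUE                      # 3-voxel speckle
  cl <- classifyPairing(m, minSize = 5, chromosome = "7")
  expect_identical(cl$verdict, "paired")
  expect_identical(cl$n_components, 1L)
  # everything below minSize -> uncallable
  tiny <- blob_mask(c(10, 10, 4), list(1:2, 1:2, 1))
  expect_identical(classifyPairing(tiny, minSize = 5,
                                   chromosome = "7")$verdict, "uncallable")
  expect_identical(classifyPairing(array(FALSE, c(5, 5, 5)),
                                   chromosome = "7")$verdict, "uncallable")
})

test_that("the single-copy Y chromosome is never classified", {
  m <- blob_mask(c(10, 10, 4), list(1:5, 1:5, 1:2))
  expect_error(classifyPairing(m, chromosome = "Y"),
               "single-copy chromosome not classifiable")
})

test_that("connectivity changes the verdict for corner-touching signals", {
  m <- array(FALSE, c(8, 8, 8))
  m[1:3, 1:3, 1:3] <- TRUE
  m[4:6, 4:6, 4:6] <- TRUE
  expect_identical(classifyPairing(m, connectivity = 26,
                                   chromosome = "2")$verdict, "paired")
  expect_identical(classifyPairing(m, connectivity = 6,
                                   chromosome = "2")$verdict, "unpaired")
})

test_that("association arithmetic matches the shared-voxel definition", {
  d <- c(20, 20, 5)
  a <- blob_mask(d, list(1:10, 1:10, 1:2))      # 200 voxels
  b <- blob_mask(d, list(6:10, 1:10, 1:2))      # 100 voxels, 100 shared
  r <- association(a, a, chrA = "1", chrB = "2")
  expect_identical(r$shared_voxels, 200L)
  expect_equal(c(r$overlap_pct_a, r$overlap_pct_b), c(100, 100))
  r2 <- association(a, b, chrA = "1", chrB = "2")
  expect_identical(r2$shared_voxels, 100L)
  expect_equal(r2$overlap_pct_a, 50)
  expect_equal(r2$overlap_pct_b, 100)
  expect_true(r2$associated)
  disj <- blob_mask(d, list(15:18, 1:10, 1:2))
  r3 <- association(a, disj, chrA = "1", chrB = "2")
  expect_identical(r3$shared_voxels, 0L)
  expect_false(r3$associated)
  expect_equal(c(r3$overlap_pct_a, r3$overlap_pct_b), c(0, 0))
  # 200 / 100 voxels with 50 shared -> 25% and 50%
  a3 <- blob_mask(d, list(1:10, 1:10, 1:2))     # 200 voxels
  b3 <- blob_mask(d, list(6:15, 1:5, 1:2))      # 100 voxels, 50 shared
  expect_identical(sum(a3 & b3), 50L)
  r4 <- association(a3, b3, chrA = "4", chrB = "5")
  expect_equal(r4$overlap_pct_a, 25)
  expect_equal(r4$overlap_pct_b, 50)
})

test_that("association rejects mismatched inputs", {
  a <- blob_mask(c(5, 5, 2), list(1:2, 1:2, 1))
  b <- blob_mask(c(6, 5, 2), list(1:2, 1:2, 1))
  expect_error(association(a, b, chrA = "1", chrB = "2"),
               "dimensions differ")
  expect_error(association(a, a, chrA = "1", chrB = "1"),
               "different chromosomes")
})

test_that("shared voxels are symmetric; overlap grows with intersection", {
  set.seed(31)
  d <- c(12, 12, 6)
  for (i in 1:20) {
    a <- random_mask(d, 0.3); b <- random_mask(d, 0.3)
    ra <- association(a, b, chrA = "1", chrB = "2")
    rb <- association(b, a, chrA = "2", chrB = "1")
    expect_identical(ra$shared_voxels, rb$shared_voxels)
  }
  # adding intersection voxels never lowers either percentage
  a <- blob_mask(d, list(1:6, 1:6, 1:3))
  b <- blob_mask(d, list(4:9, 4:9, 2:4))
  base <- association(a, b, chrA = "1", chrB = "2")
  grow <- b | blob_mask(d, list(1:3, 1:3, 1))  # new voxels inside a
  r <- association(a, grow, chrA = "1", chrB = "2")
  expect_gte(r$overlap_pct_a, base$overlap_pct_a)
})

test_that("NVP follows its defining ratio and boundary cases", {
  d <- c(30, 30, 10)
  nmask <- array(TRUE, d)                      # 9000-voxel nucleus
  nuc <- new("NucleusMask", nucleusId = "n", mask = nmask,
             spacing = c(x = 0.1, y = 0.1, z = 0.17))
  sig_arr <- blob_mask(d, list(1:10, 1:9, 1))  # 90 voxels
  sig <- new("SignalMask", nucleusId = "n", chromosome = "5",
             roundId = "r1", mask = sig_arr,
             spacing = spacing(nuc))
  call <- classifyPairing(sig)
  r <- nuclearVolumeProportion(sig, nuc, call)
  expect_identical(r$signal_kind, "two-chromosome")
  expect_equal(r$nvp_pct, 100 * 90 / 9000)
  # signal equal to the nucleus occupies 100%
  full <- new("SignalMask", nucleusId = "n", chromosome = "5",
              roundId = "r1", mask = nmask, spacing = spacing(nuc))
  expect_equal(nuclearVolumeProportion(full, nuc,
                                       classifyPairing(full))$nvp_pct, 100)
  # unpaired -> one record per component
  two <- blob_mask(d, list(1:5, 1:5, 1:2), list(20:24, 20:24, 5:6))
  sig2 <- new("SignalMask", nucleusId = "n", chromosome = "5",
              roundId = "r1", mask = two, spacing = spacing(nuc))
  r2 <- nuclearVolumeProportion(sig2, nuc, classifyPairing(sig2))
  expect_identical(nrow(r2), 2L)
  expect_true(all(r2$signal_kind == "one-chromosome"))
  expect_true(all(r2$nvp_pct > 0 & r2$nvp_pct <= 100))
  # empty nucleus is an error
  enuc <- new("NucleusMask", nucleusId = "n",
              mask = array(FALSE, d), spacing = spacing(nuc))
  expect_error(nuclearVolumeProportion(sig, enuc, call), "empty nucleus")
})

test_that("per-nucleus metrics agree with ground truth on a clean nucleus", {
  pre <- mini_preset(p = 0.5)
  spec <- do.call(nucleusSpec, c(list(pre, region = 1, seed = 61,
                                      noiseSd = 0, blurSigmaUm = 0),
                                 small_geometry))
  rec <- generateNucleus(spec)
  m <- nucleusMetrics(rec, sigma = 0)
  rc <- signalRecovery(rec, m)
  expect_true(all(rc$jaccard == 1))
  expect_true(all(rc$verdict_match))
  # associations computed for the three within-round pairs
  expect_identical(nrow(m$associations), 3L)
  gt <- rec@groundTruth$associations
  key <- function(df) paste(pmin(df$chr_a, df$chr_b),
                            pmax(df$chr_a, df$chr_b))
  expect_identical(m$associations$shared_voxels[order(key(m$associations))],
                   as.integer(gt$shared_voxels[order(key(gt))]))
})
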