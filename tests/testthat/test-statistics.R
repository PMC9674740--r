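fake_calls <- function(stage, chromosome, paired, unpaired,
                       uncallable = 0) {
  data.frame(
    stage = stage, chromosome = chromosome,
    verdict = rep(c("paired", "unpaired", "uncallable"),
                  c(paired, unpaired, uncallable)),
    stringsAsFactors = FALSE)
}

test_that("pairing tables count one- and two-signal nuclei correctly", {
  calls <- rbind(fake_calls("I", "19", 24, 2),
                 fake_calls("I", "1", 44, 19, uncallable = 3))
  tab <- buildPairingTable(calls)
  r19 <- tab[tab$chromosome == "19", ]
  expect_identical(r19$n_one_signal, 24L)
  expect_identical(r19$total, 26L)
  expect_equal(round(r19$pct_one_signal, 2), 92.31)
  r1 <- tab[tab$chromosome == "1", ]
  expect_identical(r1$total, 63L)              # uncallable excluded
  expect_equal(round(r1$pct_one_signal, 2), 69.84)
  # all-paired and all-uncallable corners
  expect_equal(buildPairingTable(
    fake_calls("II", "5", 10, 0))$pct_one_signal, 100)
  only_unc <- buildPairingTable(fake_calls("II", "5", 0, 0, 4))
  expect_identical(only_unc$total, 0L)
  expect_true(is.na(only_unc$pct_one_signal))
  expect_identical(nrow(buildPairingTable(NULL)), 0L)
})

test_that("stage summaries use unweighted means and sample SD", {
  tab <- pairingTableFromFixture()
  s1 <- stageSummary(tab, "I")
  expect_equal(round(s1$mean_paired_pct, 2), 73.83)
  expect_equal(round(s1$sd_paired_pct, 2), 6.78)
  expect_identical(s1$n_chromosomes, 20L)
  s2 <- stageSummary(tab, "II")
  expect_equal(round(s2$mean_paired_pct, 2), 84.60)
  expect_equal(round(s2$sd_paired_pct, 2), 6.40)
  # equal percentages give zero SD
  flat <- data.frame(stage = stageLabels()[1],
                     chromosome = chromosomeIds(classifiable = TRUE),
                     pct_one_signal = 80)
  expect_equal(stageSummary(flat, "I")$sd_paired_pct, 0)
  # missing chromosomes are named in the error
  expect_error(stageSummary(tab[tab$chromosome != "7", ], "I"), "7")
})

test_that("feature correlations match a direct covariance-formula oracle", {
  set.seed(99)
  tab <- pairingTableFromFixture()
  feats <- loadFixture("features")
  for (i in 1:25) {
    x <- rnorm(20); y <- rnorm(20)
    t2 <- data.frame(stage = stageLabels()[1],
                     chromosome = chromosomeIds(classifiable = TRUE),
                     pct_one_signal = y)
    f2 <- data.frame(chromosome = chromosomeIds(classifiable = TRUE),
                     size_mb = x)
    fc <- featureCorrelation(t2, f2, "I", "size_mb")
    r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    t_stat <- r_oracle * sqrt(18) / sqrt(1 - r_oracle^2)
    p_oracle <- 2 * pt(-abs(t_stat), df = 18)
    expect_equal(fc$r, r_oracle, tolerance = 1e-12)
    expect_equal(fc$p, p_oracle, tolerance = 1e-12)
  }
  # perfect linearity
  lin <- data.frame(stage = stageLabels()[1],
                    chromosome = chromosomeIds(classifiable = TRUE),
                    pct_one_signal = feats$size_mb[match(
                      chromosomeIds(classifiable = TRUE),
                      feats$chromosome)] * 0.3 + 2)
  fc <- featureCorrelation(lin, feats, "I", "size_mb")
  expect_equal(fc$r, 1, tolerance = 1e-9)
  expect_lt(fc$p, 1e-6)
  # zero-variance feature and late stages are errors
  fz <- feats; fz$size_mb <- 5
  expect_error(featureCorrelation(lin, fz, "I", "size_mb"), "undefined")
  expect_error(featureCorrelation(tab, feats, "pachytene", "size_mb"),
               "first two stages")
})

test_that("the NOR comparison is a pooled-variance Student t-test", {
  tab <- pairingTableFromFixture()
  feats <- loadFixture("features")
  nc <- norComparison(tab, feats, "I")
  # oracle: pooled t statistic computed from the group summaries
  tt <- tab[tab$stage == "spermatogonia-early-preleptotene" &
            tab$chromosome != "Y", ]
  g <- feats$nor[match(tt$chromosome, feats$chromosome)]
  a <- tt$pct_one_signal[g]; b <- tt$pct_one_signal[!g]
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  t_oracle <- (mean(a) - mean(b)) /
    sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  expect_equal(nc$t, t_oracle, tolerance = 1e-12)
  expect_identical(nc$n_nor, 6L)
  # groups with identical distributions give t = 0, p = 1
  flat <- data.frame(stage = stageLabels()[1],
                     chromosome = chromosomeIds(classifiable = TRUE),
                     pct_one_signal = rep(c(70, 80), 10))
  ff <- feats
  ff$nor <- ff$chromosome %in% as.character(1:10)
  nc0 <- norComparison(flat, ff, "I")
  expect_equal(nc0$t, 0)
  expect_equal(nc0$p, 1)
  expect_error(norComparison(tab, transform(feats, nor = chromosome == "1"),
                             "I"), "at least two")
})

test_that("NVP summaries average per-chromosome means without weighting", {
  one <- data.frame(stage = stageLabels()[1], chromosome = "3",
                    signal_kind = "one-chromosome", nvp_pct = 3.0)
  s <- nvpSummary(one)
  expect_equal(s$averages$average_nvp_pct, 3.0)
  # two chromosomes with different observation counts: unweighted
  rec <- rbind(
    data.frame(stage = "I", chromosome = "1",
               signal_kind = "one-chromosome", nvp_pct = c(1, 1, 1, 1)),
    data.frame(stage = "I", chromosome = "2",
               signal_kind = "one-chromosome", nvp_pct = 3))
  expect_equal(nvpSummary(rec)$averages$average_nvp_pct, 2)
})

test_that("Wald and Wilson intervals match their closed forms", {
  ci <- waldCI(20, 50)
  expect_equal(unname(round(ci, 3)), c(0.264, 0.536))
  w <- wilsonCI(0, 35)
  expect_equal(unname(round(w, 4)), c(0, 0.0989))
  # wilson bounds stay in [0,1] everywhere, wald need not
  set.seed(3)
  for (i in 1:50) {
    n <- sample(5:80, 1); k <- sample(0:n, 1)
    w <- wilsonCI(k, n)
    expect_true(w[["lower"]] >= 0 && w[["upper"]] <= 1)
    expect_true(w[["lower"]] <= k / n && k / n <= w[["upper"]])
    # cross-check against the score interval of prop.test
    pt <- suppressWarnings(prop.test(k, n, correct = FALSE))
    expect_equal(unname(w), pt$conf.int[1:2], tolerance = 1e-9)
  }
})

test_that("association summaries apply the weighted-mean significance rule", {
  mk <- function(a, b, k, n) data.frame(
    chr_a = a, chr_b = b,
    associated = rep(c(TRUE, FALSE), c(k, n - k)),
    overlap_pct_a = ifelse(rep(c(TRUE, FALSE), c(k, n - k)), 4, 0),
    overlap_pct_b = ifelse(rep(c(TRUE, FALSE), c(k, n - k)), 2, 0),
    stringsAsFactors = FALSE)
  rec <- rbind(mk("1", "2", 45, 50),    # high pair
               mk("1", "3", 20, 50),
               mk("2", "3", 20, 50),
               mk("4", "5", 0, 50))     # zero pair -> wilson
  s <- associationSummary(rec)
  expect_equal(s$weighted_mean, 85 / 200)
  p12 <- s$pairs[s$pairs$chr_a == "1" & s$pairs$chr_b == "2", ]
  expect_identical(p12$flag, "above_mean")
  expect_identical(p12$method, "wald")
  p45 <- s$pairs[s$pairs$chr_a == "4" & s$pairs$chr_b == "5", ]
  expect_identical(p45$method, "wilson")
  expect_identical(p45$flag, "below_mean")
  # flags partition the pairs exhaustively
  expect_true(all(s$pairs$flag %in% c("above_mean", "below_mean", "ns")))
  expect_true(all((s$pairs$lower > s$weighted_mean) ==
                  (s$pairs$flag == "above_mean")))
  expect_true(all((s$pairs$upper < s$weighted_mean) ==
                  (s$pairs$flag == "below_mean")))
  # weighted mean equals the unweighted mean when all n are equal
  expect_equal(s$weighted_mean, mean(s$pairs$p_hat))
  # bonferroni widens every interval
  sb <- associationSummary(rec, bonferroni = TRUE)
  expect_true(all(sb$pairs$upper >= s$pairs$upper - 1e-12))
  expect_true(all(sb$pairs$lower <= s$pairs$lower + 1e-12))
})
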