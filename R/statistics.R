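#' Aggregate pairing calls into a per-stage, per-chromosome count table
#'
#' One-signal nuclei are those whose homologs were called paired, and
#' two-signal nuclei those called unpaired; uncallable nuclei are excluded
#' from the totals. The one-signal percentage is undefined (NA) when a
#' cell has no callable nuclei, and is not reported for single-copy
#' chromosomes.
#'
#' @param calls data.frame of pairing calls with columns `stage`,
#'   `chromosome`, `verdict` (e.g. the `calls` element of
#'   [nucleusMetrics()] output rows bound together).
#' @return data.frame: `stage`, `chromosome`, `n_two_signal`,
#'   `n_one_signal`, `total`, `pct_one_signal`.
#' @export
buildPairingTable <- function(calls) {
  if (is.null(calls) || !nrow(calls))
    return(data.frame(stage = character(), chromosome = character(),
                      n_two_signal = integer(), n_one_signal = integer(),
                      total = integer(), pct_one_signal = numeric(),
                      stringsAsFactors = FALSE))
  key <- interaction(calls$stage, calls$chromosome, drop = TRUE)
  rows <- lapply(split(calls, key), function(g) {
    n1 <- sum(g$verdict == "paired")
    n2 <- sum(g$verdict == "unpaired")
    data.frame(stage = g$stage[1], chromosome = g$chromosome[1],
               n_two_signal = n2, n_one_signal = n1, total = n1 + n2,
               pct_one_signal = if (n1 + n2 > 0) 100 * n1 / (n1 + n2)
                                else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$stage, match(out$chromosome, chromosomeIds())), ]
}

#' Pairing count table from the packaged observed counts
#'
#' Converts the packaged one-signal/two-signal counts into the same shape
#' [buildPairingTable()] produces from computed calls. The single-copy Y
#' chromosome keeps its counts but a null percentage.
#'
#' @return data.frame as in [buildPairingTable()], plus `single_copy`.
#' @export
pairingTableFromFixture <- function() {
  x <- loadFixture("pairing_counts")
  x$pct_one_signal <- ifelse(x$single_copy, NA_real_,
                             100 * x$n_one_signal / x$total)
  x[, c("stage", "chromosome", "n_two_signal", "n_one_signal", "total",
        "pct_one_signal", "single_copy")]
}

#' Mean and SD of per-chromosome pairing percentages at one stage
#'
#' Unweighted mean and sample (n-1 denominator) standard deviation over
#' the 20 classifiable chromosomes (autosomes 1-19 plus X).
#'
#' @param table A pairing count table ([buildPairingTable()] or
#'   [pairingTableFromFixture()]).
#' @param stage Stage label (canonical or `I`-`IV` alias).
#' @return data.frame row: `stage`, `mean_paired_pct`, `sd_paired_pct`,
#'   `n_chromosomes`.
#' @export
stageSummary <- function(table, stage) {
  stage <- normalizeStage(stage)
  tt <- table[table$stage == stage &
              table$chromosome %in% chromosomeIds(classifiable = TRUE), ]
  missing <- setdiff(chromosomeIds(classifiable = TRUE), tt$chromosome)
  if (length(missing))
    stop("stage ", stage, " is missing chromosome(s): ",
         paste(missing, collapse = ", "))
  p <- tt$pct_one_signal
  if (any(is.na(p)))
    stop("stage ", stage, " has chromosomes with no callable nuclei: ",
         paste(tt$chromosome[is.na(p)], collapse = ", "))
  data.frame(stage = stage, mean_paired_pct = mean(p),
             sd_paired_pct = sd(p), n_chromosomes = length(p),
             stringsAsFactors = FALSE)
}

#' Pearson correlation of a chromosome feature with pairing percentage
#'
#' Correlates one genomic feature (size, %GC or gene density) with the
#' per-chromosome paired percentage at one of the first two stages (later
#' stages have no unpaired chromosomes, so the correlation is degenerate).
#' The two-sided p-value uses the t distribution with n-2 degrees of
#' freedom.
#'
#' @param table Pairing count table.
#' @param features Feature table ([loadFixture]`("features")`).
#' @param stage Stage label (first two stages only).
#' @param feature One of `"size_mb"`, `"gc_percent"`, `"gene_density"`.
#' @return data.frame row: `feature`, `stage`, `r`, `p`, `n`.
#' @export
featureCorrelation <- function(table, features,
                               stage = "spermatogonia-early-preleptotene",
                               feature = c("size_mb", "gc_percent",
                                           "gene_density")) {
  feature <- match.arg(feature)
  stage <- normalizeStage(stage)
  if (!stage %in% stageLabels()[1:2])
    stop("correlations are defined for the first two stages only")
  tt <- table[table$stage == stage &
              table$chromosome %in% chromosomeIds(classifiable = TRUE), ]
  x <- features[[feature]][match(tt$chromosome, features$chromosome)]
  y <- tt$pct_one_signal
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 2 || sd(x) == 0)
    stop("correlation undefined: zero-variance feature")
  ct <- cor.test(x, y, method = "pearson")
  data.frame(feature = feature, stage = stage,
             r = unname(ct$estimate), p = ct$p.value, n = length(x),
             stringsAsFactors = FALSE)
}

#' Compare pairing of NOR-bearing vs non-NOR-bearing chromosomes
#'
#' Two-sample pooled-variance Student t-test (two-sided) of per-chromosome
#' paired percentages between the NOR-bearing group (chromosomes 11, 12,
#' 15, 16, 18, 19) and the remaining classifiable chromosomes. A Welch
#' test is available via `pooled = FALSE`.
#'
#' @param table Pairing count table.
#' @param features Feature table with the `nor` column.
#' @param stage Stage label.
#' @param pooled Use the pooled-variance Student test (default).
#' @return data.frame row: `stage`, `t`, `p`, `mean_nor`, `mean_other`,
#'   `n_nor`, `n_other`.
#' @export
norComparison <- function(table, features,
                          stage = "spermatogonia-early-preleptotene",
                          pooled = TRUE) {
  stage <- normalizeStage(stage)
  tt <- table[table$stage == stage &
              table$chromosome %in% chromosomeIds(classifiable = TRUE), ]
  nor <- features$nor[match(tt$chromosome, features$chromosome)]
  a <- tt$pct_one_signal[nor]
  b <- tt$pct_one_signal[!nor]
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least two chromosomes")
  ht <- t.test(a, b, var.equal = pooled)
  data.frame(stage = stage, t = unname(ht$statistic), p = ht$p.value,
             mean_nor = mean(a), mean_other = mean(b),
             n_nor = length(a), n_other = length(b),
             stringsAsFactors = FALSE)
}

#' Summarise nuclear volume proportions per chromosome and signal kind
#'
#' Per-chromosome mean NVP by signal kind, plus the column average — the
#' unweighted mean over the chromosome rows present for that kind.
#'
#' @param records data.frame with columns `stage`, `chromosome`,
#'   `signal_kind`, `nvp_pct` (computed NVP records, or the packaged NVP
#'   table whose rows are already per-chromosome means).
#' @return List with `perChromosome` (data.frame `stage`, `chromosome`,
#'   `signal_kind`, `n`, `mean_nvp_pct`) and `averages` (data.frame
#'   `stage`, `signal_kind`, `average_nvp_pct`, `n_chromosomes`).
#' @export
nvpSummary <- function(records) {
  stopifnot(all(c("stage", "chromosome", "signal_kind", "nvp_pct") %in%
                names(records)))
  key <- interaction(records$stage, records$chromosome,
                     records$signal_kind, drop = TRUE)
  per <- do.call(rbind, c(lapply(split(records, key), function(g)
    data.frame(stage = g$stage[1], chromosome = g$chromosome[1],
               signal_kind = g$signal_kind[1], n = nrow(g),
               mean_nvp_pct = mean(g$nvp_pct),
               stringsAsFactors = FALSE)),
    list(make.row.names = FALSE)))
  per <- per[order(per$stage, per$signal_kind,
                   match(per$chromosome, chromosomeIds())), ]
  key2 <- interaction(per$stage, per$signal_kind, drop = TRUE)
  avg <- do.call(rbind, c(lapply(split(per, key2), function(g)
    data.frame(stage = g$stage[1], signal_kind = g$signal_kind[1],
               average_nvp_pct = mean(g$mean_nvp_pct),
               n_chromosomes = nrow(g), stringsAsFactors = FALSE)),
    list(make.row.names = FALSE)))
  list(perChromosome = per, averages = avg)
}

#' Wald asymptotic confidence interval for a proportion
#'
#' `p_hat +/- z * sqrt(p_hat (1 - p_hat) / n)`, unclipped.
#'
#' @param k Successes.
#' @param n Trials (> 0).
#' @param conf Confidence level.
#' @return Named vector `lower`, `upper`.
#' @export
waldCI <- function(k, n, conf = 0.95) {
  stopifnot(n > 0, k >= 0, k <= n)
  k <- unname(k); n <- unname(n)
  p <- k / n
  z <- qnorm(1 - (1 - conf) / 2)
  hw <- z * sqrt(p * (1 - p) / n)
  c(lower = p - hw, upper = p + hw)
}

#' Wilson score confidence interval for a proportion
#'
#' Always within `[0, 1]`; used in place of the Wald interval when no
#' successes were observed.
#'
#' @inheritParams waldCI
#' @return Named vector `lower`, `upper`.
#' @export
wilsonCI <- function(k, n, conf = 0.95) {
  stopifnot(n > 0, k >= 0, k <= n)
  k <- unname(k); n <- unname(n)
  p <- k / n
  z <- qnorm(1 - (1 - conf) / 2)
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - hw), upper = min(1, centre + hw))
}

#' Summarise heterologous associations with confidence intervals
#'
#' Per chromosome pair: association frequency `k/n`, a 95% confidence
#' interval (Wald asymptotic; Wilson score whenever `k = 0`), and a
#' significance flag against the overall weighted mean association
#' frequency (`sum(k)/sum(n)`): a pair whose interval lies entirely above
#' the weighted mean is `above_mean`, entirely below is `below_mean`,
#' otherwise `ns`. Also reports mean directional overlap percentages.
#'
#' @param records Association records (rows like [association()] output,
#'   bound over nuclei), with columns `chr_a`, `chr_b`, `associated`,
#'   `overlap_pct_a`, `overlap_pct_b`.
#' @param conf Confidence level (significance level 0.05 by default).
#' @param bonferroni Optional multiplicity correction across pairs: widens
#'   the intervals to level `1 - (1-conf)/npairs`. Off by default, which
#'   matches the uncorrected published procedure.
#' @return List: `pairs` (data.frame `chr_a`, `chr_b`, `k`, `n`, `p_hat`,
#'   `lower`, `upper`, `method`, `flag`, `mean_overlap_pct`),
#'   `weighted_mean` (proportion), `mean_overlap_pct` (mean of all
#'   directional overlap percentages).
#' @export
associationSummary <- function(records, conf = 0.95, bonferroni = FALSE) {
  stopifnot(all(c("chr_a", "chr_b", "associated") %in% names(records)))
  a <- pmin(records$chr_a, records$chr_b)
  b <- pmax(records$chr_a, records$chr_b)
  key <- paste(a, b, sep = "|")
  grp <- split(records, key)
  grp <- grp[vapply(grp, nrow, 0L) > 0]
  k <- vapply(grp, function(g) sum(g$associated), 0)
  n <- vapply(grp, nrow, 0L)
  wmean <- sum(k) / sum(n)
  level <- if (bonferroni) 1 - (1 - conf) / length(grp) else conf
  rows <- lapply(seq_along(grp), function(i) {
    g <- grp[[i]]
    method <- if (k[i] == 0) "wilson" else "wald"
    ci <- if (method == "wilson") wilsonCI(k[i], n[i], level)
          else waldCI(k[i], n[i], level)
    flag <- if (ci[["lower"]] > wmean) "above_mean"
            else if (ci[["upper"]] < wmean) "below_mean" else "ns"
    data.frame(chr_a = min(g$chr_a[1], g$chr_b[1]),
               chr_b = max(g$chr_a[1], g$chr_b[1]),
               k = k[i], n = n[i], p_hat = k[i] / n[i],
               lower = ci[["lower"]], upper = ci[["upper"]],
               method = method, flag = flag,
               mean_overlap_pct =
                 mean(c(g$overlap_pct_a, g$overlap_pct_b)),
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  pairs <- pairs[order(match(pairs$chr_a, chromosomeIds()),
                       match(pairs$chr_b, chromosomeIds())), ]
  list(pairs = pairs, weighted_mean = wmean,
       mean_overlap_pct = mean(c(records$overlap_pct_a,
                                 records$overlap_pct_b)))
}
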