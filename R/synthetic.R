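#' Fluorochrome channel names used by the simulated hybridization rounds
#' @noRd
.fluorochromes <- c("DEAC", "FITC", "TexasRed")
.counterstain_channel <- "DAPI"

#' Probe layout of the simulated multiprobe device
#'
#' The simulated assay mirrors a multiprobe chromosome-painting device:
#' each nucleus sits under one of seven regions, and each hybridization
#' round paints three chromosomes per region with three fluorochromes, so
#' that a nucleus accumulates nine distinct chromosomes over three rounds
#' and the seven regions jointly cover the whole karyotype in every round.
#' The lymphocyte preset uses a single round over five regions covering the
#' 15 chromosomes assayed in somatic cells.
#'
#' @param stage Canonical stage label or `I`-`IV` alias.
#' @return data.frame with columns `region`, `round`, `channel`,
#'   `chromosome`.
#' @export
probeLayout <- function(stage = "spermatogonia-early-preleptotene") {
  stage <- normalizeStage(stage)
  if (stage == "lymphocyte") {
    chroms <- c("1", "3", "4", "6", "7", "8", "9", "10", "11", "12",
                "14", "16", "17", "18", "19")
    nreg <- 5L
    out <- data.frame(
      region = rep(seq_len(nreg), each = 3L),
      round = "r1",
      channel = rep(.fluorochromes, nreg),
      chromosome = chroms,
      stringsAsFactors = FALSE)
    return(out)
  }
  chroms <- chromosomeIds()
  nreg <- 7L
  rows <- list()
  for (rd in 1:3) {
    for (reg in seq_len(nreg)) {
      # round rd shifts the slot blocks by rd-1 regions so each region
      # sees nine distinct chromosomes across the three rounds
      block <- ((reg - 1 + rd - 1) %% nreg)
      ids <- chroms[(block * 3 + 1):(block * 3 + 3)]
      rows[[length(rows) + 1]] <- data.frame(
        region = reg, round = paste0("r", rd),
        channel = .fluorochromes, chromosome = ids,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Stage preset: per-chromosome pairing probabilities and territory sizes
#'
#' Builds the simulation conditions for one cell stage from the packaged
#' observed tables: the per-chromosome probability that the two homologs
#' form one continuous signal is the observed one-signal fraction for that
#' stage, and territory sizes (as nuclear volume proportion, NVP) are the
#' observed per-chromosome mean NVPs of unpaired and paired signals. The
#' pachytene and round-spermatid presets therefore have all pairing
#' probabilities equal to 1. The lymphocyte preset uses a uniform pairing
#' probability (default the observed somatic mean of 19.47%) over the 15
#' chromosomes assayed in lymphocytes.
#'
#' @param stage Canonical stage label or `I`-`IV` alias.
#' @param lymphocytePairing Uniform pairing probability for the lymphocyte
#'   preset; ignored for germ-cell stages.
#' @return A list of class `StagePreset` with elements `stage`,
#'   `chromosomes`, `copies`, `pairingProb`, `nvpOne`, `nvpTwo`, `layout`.
#' @export
#' @examples
#' p <- stagePreset("spermatogonia-early-preleptotene")
#' p$pairingProb[["19"]]  # 24/26
#' stagePreset("pachytene")$pairingProb[["1"]]
stagePreset <- function(stage, lymphocytePairing = 0.1947) {
  stage <- normalizeStage(stage)
  counts <- loadFixture("pairing_counts")
  nvp <- loadFixture("nvp")
  layout <- probeLayout(stage)
  chroms <- unique(layout$chromosome)
  copies <- setNames(ifelse(chroms == "Y", 1L, 2L), chroms)
  if (stage == "lymphocyte") {
    if (lymphocytePairing < 0 || lymphocytePairing > 1)
      stop("lymphocytePairing must be in [0, 1]")
    pp <- setNames(rep(lymphocytePairing, length(chroms)), chroms)
    nvp_stage <- "spermatogonia-early-preleptotene"
  } else {
    cc <- counts[counts$stage == stage, ]
    pp <- setNames(cc$n_one_signal / (cc$n_one_signal + cc$n_two_signal),
                   cc$chromosome)[chroms]
    pp[["Y"]] <- NA_real_  # single copy, never classified
    # NVP observations exist for the first two stages only; later stages
    # reuse the mid-preleptotene-zygotene territory sizes
    nvp_stage <- if (stage %in% stageLabels()[1:2]) stage else
      "mid-preleptotene-zygotene"
  }
  nv <- nvp[nvp$stage == nvp_stage, ]
  one <- setNames(nv$nvp_pct[nv$signal_kind == "one-chromosome"],
                  nv$chromosome[nv$signal_kind == "one-chromosome"])
  two <- setNames(nv$nvp_pct[nv$signal_kind == "two-chromosome"],
                  nv$chromosome[nv$signal_kind == "two-chromosome"])
  structure(list(stage = stage, chromosomes = chroms, copies = copies,
                 pairingProb = pp, nvpOne = one[chroms],
                 nvpTwo = two[chroms], layout = layout),
            class = "StagePreset")
}

#' Specification of one synthetic nucleus
#'
#' Collects every parameter of the simulated imaging experiment for a
#' single nucleus: ellipsoidal nucleus geometry, voxel spacing (anisotropic
#' by default, 0.17 um between optical sections), the channel/chromosome
#' layout of one probe region, per-chromosome territory sizes and pairing
#' probabilities, heterologous association probabilities, optics (Gaussian
#' blur approximating the point spread function, additive Gaussian noise),
#' and an explicit RNG seed.
#'
#' @param preset A [stagePreset()] object supplying pairing probabilities,
#'   territory sizes and the probe layout.
#' @param region Probe region the nucleus sits under (selects which nine
#'   chromosomes are painted).
#' @param seed Integer RNG seed (required; the generator keeps no global
#'   random state).
#' @param id Nucleus identifier.
#' @param semiaxesUm Ellipsoid semiaxes `c(x, y, z)` in micrometres.
#' @param spacingUm Voxel spacing `c(x, y, z)` in micrometres.
#' @param assocDefault Default probability that two heterologous
#'   chromosomes painted in the same round share at least one voxel.
#'   Default 0.411, the observed premeiotic mean association frequency.
#' @param assocPairs Optional data.frame `chr_a`, `chr_b`, `prob`
#'   overriding `assocDefault` for specific pairs.
#' @param pairedVolumeFactor Volume of a paired (two-homolog) signal
#'   relative to a single-homolog signal when the preset supplies no
#'   per-chromosome paired NVP. Default 1.62, the observed ratio of paired
#'   to unpaired mean NVP.
#' @param irregularity Blob growth irregularity in `[0, 1]` (0 compact,
#'   1 ragged).
#' @param separationVox Minimum background gap, in voxels (Chebyshev), by
#'   which unpaired homolog copies and non-associated heterologous
#'   territories are separated at placement. Must be at least 2 (which
#'   already guarantees non-adjacency under 26-connectivity); the default
#'   of 4 voxels (0.4 um at the default xy spacing) keeps distinct
#'   territories resolvable under the modelled point spread function.
#' @param noiseSd Additive Gaussian noise standard deviation (intensities
#'   are on a 0-1 scale; territory amplitude is 0.8).
#' @param blurSigmaUm Gaussian blur sigma `c(x, y, z)` in micrometres.
#' @param counterstain Include a nuclear counterstain channel (needed for
#'   nucleus segmentation).
#' @return A list of class `NucleusSpec`.
#' @export
nucleusSpec <- function(preset, region = 1L, seed, id = "nucleus-1",
                        semiaxesUm = c(3.5, 3.0, 2.5),
                        spacingUm = c(x = 0.1, y = 0.1, z = 0.17),
                        assocDefault = 0.411, assocPairs = NULL,
                        pairedVolumeFactor = 1.62,
                        irregularity = 0.3, separationVox = 4,
                        noiseSd = 0.08,
                        blurSigmaUm = c(0.08, 0.08, 0.21),
                        counterstain = TRUE) {
  if (missing(seed)) stop("an explicit integer seed is required")
  lay <- preset$layout[preset$layout$region == region, ]
  if (!nrow(lay)) stop("region ", region, " not present in preset layout")
  chroms <- unique(lay$chromosome)
  nvpTwo <- preset$nvpTwo[chroms]
  miss <- is.na(nvpTwo)
  nvpTwo[miss] <- preset$nvpOne[chroms][miss] * pairedVolumeFactor
  spec <- structure(list(
    id = id, stage = preset$stage, region = region,
    semiaxesUm = unname(semiaxesUm),
    spacingUm = c(x = unname(spacingUm[1]), y = unname(spacingUm[2]),
                  z = unname(spacingUm[3])),
    channels = lay[, c("round", "channel", "chromosome")],
    chromosomes = chroms,
    copies = preset$copies[chroms],
    pairingProb = preset$pairingProb[chroms],
    nvpOne = preset$nvpOne[chroms],
    nvpTwo = nvpTwo,
    assocDefault = assocDefault,
    assocPairs = assocPairs,
    irregularity = irregularity,
    separationVox = as.integer(separationVox),
    noiseSd = noiseSd,
    blurSigmaUm = unname(rep_len(blurSigmaUm, 3)),
    counterstain = isTRUE(counterstain),
    seed = as.integer(seed)), class = "NucleusSpec")
  validateNucleusSpec(spec)
  spec
}

#' Validate a NucleusSpec
#'
#' @param spec A `NucleusSpec` list.
#' @return Invisibly `TRUE`; stops with a message on the first violated
#'   invariant.
#' @export
validateNucleusSpec <- function(spec) {
  stopifnot(inherits(spec, "NucleusSpec"))
  if (length(spec$semiaxesUm) != 3 || any(!is.finite(spec$semiaxesUm)) ||
      any(spec$semiaxesUm <= 0))
    stop("semiaxes must be three strictly positive lengths")
  if (any(spec$spacingUm <= 0)) stop("voxel spacing must be positive")
  pp <- spec$pairingProb[!is.na(spec$pairingProb)]
  if (any(pp < 0 | pp > 1)) stop("pairing probabilities must be in [0, 1]")
  if (spec$assocDefault < 0 || spec$assocDefault > 1)
    stop("association probabilities must be in [0, 1]")
  if (!is.null(spec$assocPairs) &&
      any(spec$assocPairs$prob < 0 | spec$assocPairs$prob > 1))
    stop("association probabilities must be in [0, 1]")
  if (spec$irregularity < 0 || spec$irregularity > 1)
    stop("irregularity must be in [0, 1]")
  if (spec$separationVox < 2)
    stop("separationVox must be at least 2 voxels")
  if (spec$noiseSd < 0) stop("noiseSd must be non-negative")
  dup <- tapply(spec$channels$chromosome, spec$channels$round,
                anyDuplicated)
  if (any(dup > 0))
    stop("chromosome ids must be unique per round")
  if (any(spec$semiaxesUm < spec$spacingUm))
    stop("degenerate semiaxes: smaller than one voxel")
  invisible(TRUE)
}

.assoc_prob <- function(spec, a, b) {
  if (!is.null(spec$assocPairs)) {
    ap <- spec$assocPairs
    hit <- (ap$chr_a == a & ap$chr_b == b) | (ap$chr_a == b & ap$chr_b == a)
    if (any(hit)) return(ap$prob[which(hit)[1]])
  }
  spec$assocDefault
}

.ellipsoid_mask <- function(dims, center, semi_vox) {
  ey <- ((seq_len(dims[1]) - center[1]) / semi_vox[1])^2
  ex <- ((seq_len(dims[2]) - center[2]) / semi_vox[2])^2
  ez <- ((seq_len(dims[3]) - center[3]) / semi_vox[3])^2
  outer(outer(ey, ex, "+"), ez, "+") <= 1
}

.grow_with_retries <- function(allowed, dims, seed_pool, target,
                               irregularity, retries = 20L) {
  # best-effort placement: territories in crowded nuclei may fall a
  # little short of their nominal volume (biological size variability);
  # anything below 80% of target counts as a placement failure
  seed_pool <- seed_pool[allowed[seed_pool]]
  if (!length(seed_pool)) return(NULL)
  best <- integer(0)
  for (r in seq_len(retries)) {
    s <- if (length(seed_pool) == 1) seed_pool else sample(seed_pool, 1)
    idx <- cpp_grow_blob(allowed, dims, s - 1L, as.integer(target),
                         irregularity)
    if (length(idx) == target) return(idx)
    if (length(idx) > length(best)) best <- idx
  }
  if (length(best) >= 0.8 * target) best else NULL
}

# grow from a preferred seed pool (e.g. inside an association partner),
# falling back to seeding anywhere in the allowed region; the realized
# configuration, not the intent, becomes ground truth
.grow_fallback <- function(allowed, dims, seed_pool, target,
                           irregularity) {
  blob <- .grow_with_retries(allowed, dims, seed_pool, target,
                             irregularity)
  if (is.null(blob)) {
    pool <- which(allowed)
    if (!identical(seed_pool, pool))
      blob <- .grow_with_retries(allowed, dims, pool, target,
                                 irregularity)
  }
  blob
}

#' Generate one synthetic nucleus with ground truth
#'
#' Simulates the 3D image stacks of one nucleus: an ellipsoidal nucleus,
#' irregular blob-shaped chromosome territories grown by seeded stochastic
#' aggregation, homolog pairing with the specified per-chromosome
#' probability, controlled heterologous association, Gaussian blur and
#' additive Gaussian noise. Paired homologs are generated as one connected
#' voxel set (the two copy sets overlap and their union is 6-connected);
#' unpaired copies are separated by a background gap of at least two
#' voxels, so the pairing ground truth is unambiguous under both 6- and
#' 26-connectivity.
#'
#' @param spec A [nucleusSpec()] object.
#' @return A [NucleusRecord-class] whose `groundTruth` list contains
#'   `dims`, `nucleus` (voxel indices), `territories` (per chromosome:
#'   `round`, `paired`, `copies` — a list of voxel index vectors — and
#'   `union`), and `associations` (data.frame of within-round heterologous
#'   pairs with realized shared voxel counts).
#' @export
#' @examples
#' pre <- stagePreset("pachytene")
#' rec <- generateNucleus(nucleusSpec(pre, region = 1, seed = 11,
#'   semiaxesUm = c(2, 2, 1.5)))
#' rec
generateNucleus <- function(spec) {
  validateNucleusSpec(spec)
  set.seed(spec$seed)
  sp <- spec$spacingUm
  semi <- spec$semiaxesUm                     # (x, y, z)
  # array axis order (y, x, z)
  sp_axes <- c(sp[["y"]], sp[["x"]], sp[["z"]])
  semi_axes <- c(semi[2], semi[1], semi[3])
  semi_vox <- semi_axes / sp_axes
  sigma_vox <- c(spec$blurSigmaUm[2], spec$blurSigmaUm[1],
                 spec$blurSigmaUm[3]) / sp_axes
  margin <- pmax(4, ceiling(3 * sigma_vox)) + 1
  dims <- as.integer(2 * ceiling(semi_vox) + 2 * margin + 1)
  center <- (dims + 1) / 2
  nuc_mask <- .ellipsoid_mask(dims, center, semi_vox)
  nuc_idx <- which(nuc_mask)
  n_nuc <- length(nuc_idx)
  if (n_nuc == 0) stop("degenerate semiaxes: empty nucleus")

  v_one <- pmax(round(spec$nvpOne / 100 * n_nuc), 5)
  v_two <- pmax(round(spec$nvpTwo / 100 * n_nuc), v_one + 1)
  worst <- ifelse(spec$copies == 2, pmax(v_two, 2 * v_one), v_one)
  per_round <- tapply(worst[spec$channels$chromosome],
                      spec$channels$round, sum)
  if (any(worst > n_nuc) || any(per_round > 0.6 * n_nuc))
    stop("territory target volume exceeds nucleus capacity")

  territories <- list()
  assoc_rows <- list()
  stacks <- list()
  rounds <- unique(spec$channels$round)
  for (rd in rounds) {
    lay <- spec$channels[spec$channels$round == rd, ]
    chroms <- lay$chromosome
    # association draws for the within-round heterologous pairs
    drawn <- list()
    if (length(chroms) > 1) {
      prs <- utils::combn(chroms, 2)
      for (p in seq_len(ncol(prs))) {
        a <- prs[1, p]; b <- prs[2, p]
        drawn[[paste(a, b, sep = "|")]] <-
          runif(1) < .assoc_prob(spec, a, b)
      }
    }
    placed <- character(0)
    for (ci in seq_along(chroms)) {
      cid <- chroms[ci]
      assoc_with <- placed[vapply(placed, function(d)
        isTRUE(drawn[[paste(d, cid, sep = "|")]]) ||
        isTRUE(drawn[[paste(cid, d, sep = "|")]]), TRUE)]
      nonassoc <- setdiff(placed, assoc_with)
      allowed <- nuc_mask
      if (length(nonassoc)) {
        block <- array(FALSE, dims)
        block[unlist(lapply(territories[nonassoc], `[[`, "union"))] <- TRUE
        allowed <- allowed & !dilate3d(block, spec$separationVox)
      }
      seed_pool <- if (length(assoc_with)) {
        pool <- territories[[assoc_with[1]]]$union
        if (any(allowed[pool])) pool else which(allowed)
      } else which(allowed)
      paired <- if (spec$copies[[cid]] == 2)
        runif(1) < spec$pairingProb[[cid]] else NA
      if (isTRUE(paired)) {
        blob <- .grow_fallback(allowed, dims, seed_pool,
                                   v_two[[cid]], spec$irregularity)
        if (is.null(blob))
          stop("could not place paired territory for chromosome ", cid)
        copies <- list(blob[seq_len(v_one[[cid]])],
                       blob[seq.int(length(blob) - v_one[[cid]] + 1,
                                    length(blob))])
        uni <- blob
      } else if (identical(paired, FALSE)) {
        blobA <- .grow_fallback(allowed, dims, seed_pool,
                                    v_one[[cid]], spec$irregularity)
        if (is.null(blobA))
          stop("could not place territory for chromosome ", cid)
        maskA <- array(FALSE, dims); maskA[blobA] <- TRUE
        allowedB <- allowed & !dilate3d(maskA, spec$separationVox)
        blobB <- .grow_with_retries(allowedB, dims, which(allowedB),
                                    v_one[[cid]], spec$irregularity)
        if (is.null(blobB))
          stop("could not place second homolog for chromosome ", cid)
        copies <- list(blobA, blobB)
        uni <- c(blobA, blobB)
      } else {
        blob <- .grow_fallback(allowed, dims, seed_pool,
                                   v_one[[cid]], spec$irregularity)
        if (is.null(blob))
          stop("could not place territory for chromosome ", cid)
        copies <- list(blob)
        uni <- blob
      }
      for (d in placed) {
        shared <- length(intersect(uni, territories[[d]]$union))
        assoc_rows[[length(assoc_rows) + 1]] <- data.frame(
          round = rd, chr_a = d, chr_b = cid,
          associated = shared > 0, shared_voxels = shared,
          stringsAsFactors = FALSE)
      }
      territories[[cid]] <- list(round = rd, paired = paired,
                                 copies = copies, union = uni)
      placed <- c(placed, cid)
    }
    # render channels
    arrs <- list()
    for (ci in seq_len(nrow(lay))) {
      a <- array(0, dims)
      a[territories[[lay$chromosome[ci]]]$union] <- 0.8
      arrs[[lay$channel[ci]]] <- a
    }
    cmap <- setNames(lay$chromosome, lay$channel)
    if (spec$counterstain) {
      a <- array(0, dims)
      a[nuc_idx] <- 0.7
      arrs[[.counterstain_channel]] <- a
      cmap <- c(cmap, setNames(NA_character_, .counterstain_channel))
    }
    for (nm in names(arrs)) {
      a <- arrs[[nm]]
      if (any(sigma_vox > 0)) a <- gaussianSmooth3d(a, sigma_vox)
      if (spec$noiseSd > 0)
        a <- a + rnorm(length(a), 0, spec$noiseSd)
      arrs[[nm]] <- array(pmin(pmax(a, 0), 1), dims)
    }
    stacks[[rd]] <- new("VoxelStack", channels = arrs,
                        spacing = sp, roundId = rd, channelMap = cmap)
  }
  truth <- list(dims = dims, spacing = sp, nucleus = nuc_idx,
                territories = territories,
                associations = if (length(assoc_rows))
                  do.call(rbind, assoc_rows) else
                  data.frame(round = character(), chr_a = character(),
                             chr_b = character(), associated = logical(),
                             shared_voxels = integer()))
  new("NucleusRecord", nucleusId = spec$id, stage = spec$stage,
      stacks = stacks, groundTruth = truth)
}

#' Generate a population of synthetic nuclei
#'
#' Draws `nCells` independent nuclei from a stage preset. Nuclei are
#' assigned to probe regions round-robin, so each chromosome is observed
#' in the subset of nuclei whose region paints it; per-nucleus seeds are
#' derived from `seed`, making the population reproducible and identical
#' to what [runPipeline()] generates internally.
#'
#' Note that stacks are kept in memory; for large populations prefer
#' [runPipeline()], which processes nuclei one at a time.
#'
#' @param preset A [stagePreset()].
#' @param nCells Number of nuclei (>= 0).
#' @param seed Integer master seed.
#' @param ... Further arguments passed to [nucleusSpec()].
#' @return List of [NucleusRecord-class] objects.
#' @export
generatePopulation <- function(preset, nCells, seed, ...) {
  stopifnot(nCells >= 0)
  if (nCells == 0) return(list())
  plan <- populationPlan(preset, nCells, seed)
  lapply(seq_len(nCells), function(i) {
    generateNucleus(nucleusSpec(preset, region = plan$region[i],
                                seed = plan$seed[i],
                                id = plan$nucleus_id[i], ...))
  })
}

#' Deterministic per-nucleus plan (region assignment and seeds)
#'
#' @param preset A [stagePreset()].
#' @param nCells Number of nuclei.
#' @param seed Integer master seed.
#' @return data.frame with `nucleus_id`, `region`, `seed`.
#' @export
populationPlan <- function(preset, nCells, seed) {
  nreg <- max(preset$layout$region)
  set.seed(seed)
  data.frame(
    nucleus_id = sprintf("%s-%04d", substr(preset$stage, 1, 4),
                         seq_len(nCells)),
    region = ((seq_len(nCells) - 1L) %% nreg) + 1L,
    seed = sample.int(.Machine$integer.max - 1L, nCells),
    stringsAsFactors = FALSE)
}
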