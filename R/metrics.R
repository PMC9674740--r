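#' Classify homolog pairing from a signal mask
#'
#' Two homologous chromosomes are called *paired* when all voxels of the
#' chromosome's signal form one continuous group of voxels, and *unpaired*
#' when they form two or more separate voxel groups sharing no voxel.
#' Components smaller than `minSize` voxels are discarded first; a mask
#' with no retained component is *uncallable*.
#'
#' @param mask A [SignalMask-class] (or logical 3D array).
#' @param minSize Minimum retained component size, voxels.
#' @param connectivity Voxel connectivity defining "continuous" (6, 18 or
#'   26; default 26, i.e. corner-touching voxels are continuous).
#' @param chromosome Chromosome id (taken from the mask if available).
#'   Single-copy chromosomes (Y) are not classifiable and raise an error.
#' @return One-row data.frame: `nucleus_id`, `chromosome`, `round`,
#'   `verdict` (`paired`/`unpaired`/`uncallable`), `n_components`,
#'   `component_voxels` (comma-separated, decreasing), `total_voxels`,
#'   `connectivity`.
#' @export
#' @examples
#' m <- array(FALSE, c(8, 8, 4)); m[2:4, 2:4, 2] <- TRUE
#' classifyPairing(m, chromosome = "1")$verdict
classifyPairing <- function(mask, minSize = 5, connectivity = 26,
                            chromosome = NULL) {
  nid <- "nucleus"; rid <- NA_character_
  if (is(mask, "SignalMask")) {
    if (is.null(chromosome)) chromosome <- mask@chromosome
    nid <- mask@nucleusId; rid <- mask@roundId
    mask <- maskArray(mask)
  }
  if (is.null(chromosome)) chromosome <- NA_character_
  if (identical(chromosome, "Y"))
    stop("single-copy chromosome not classifiable")
  lab <- labelComponents(mask, connectivity)
  sizes <- lab$sizes[lab$sizes >= minSize]
  verdict <- if (length(sizes) == 0) "uncallable"
             else if (length(sizes) == 1) "paired" else "unpaired"
  data.frame(nucleus_id = nid, chromosome = as.character(chromosome),
             round = rid, verdict = verdict,
             n_components = length(sizes),
             component_voxels = paste(sizes, collapse = ","),
             total_voxels = sum(sizes), connectivity = connectivity,
             stringsAsFactors = FALSE)
}

#' Heterologous association and overlap of two territories
#'
#' Two different chromosomes are associated when their territories share
#' at least one voxel. The overlap percentage is directional: the shared
#' voxel count expressed as a percentage of each territory's own voxels.
#'
#' @param maskA,maskB [SignalMask-class] objects (or logical 3D arrays) of
#'   two different chromosomes, same dimensions.
#' @param chrA,chrB Chromosome ids (taken from the masks if available).
#' @return One-row data.frame: `nucleus_id`, `round`, `chr_a`, `chr_b`,
#'   `voxels_a`, `voxels_b`, `shared_voxels`, `overlap_pct_a`,
#'   `overlap_pct_b`, `associated`.
#' @export
association <- function(maskA, maskB, chrA = NULL, chrB = NULL) {
  nid <- "nucleus"; rid <- NA_character_
  if (is(maskA, "SignalMask")) {
    if (is.null(chrA)) chrA <- maskA@chromosome
    nid <- maskA@nucleusId; rid <- maskA@roundId
    maskA <- maskArray(maskA)
  }
  if (is(maskB, "SignalMask")) {
    if (is.null(chrB)) chrB <- maskB@chromosome
    maskB <- maskArray(maskB)
  }
  if (!identical(dim(maskA), dim(maskB)))
    stop("mask dimensions differ")
  if (!is.null(chrA) && !is.null(chrB) && identical(chrA, chrB))
    stop("association requires two different chromosomes")
  va <- sum(maskA); vb <- sum(maskB)
  shared <- sum(maskA & maskB)
  data.frame(nucleus_id = nid, round = rid,
             chr_a = as.character(chrA %||% NA),
             chr_b = as.character(chrB %||% NA),
             voxels_a = va, voxels_b = vb, shared_voxels = shared,
             overlap_pct_a = if (va > 0) 100 * shared / va else 0,
             overlap_pct_b = if (vb > 0) 100 * shared / vb else 0,
             associated = shared > 0, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Nuclear volume proportion of a signal
#'
#' The NVP of a signal is 100 x (signal voxels) / (nucleus voxels).
#' A paired signal is one signal composed by two chromosomes; an unpaired
#' chromosome contributes one record per retained component (each a signal
#' composed by one chromosome). Physical spacing cancels in the ratio.
#'
#' @param signal A [SignalMask-class].
#' @param nucleus A [NucleusMask-class], non-empty, same frame.
#' @param call A one-row pairing-call data.frame from [classifyPairing()],
#'   or `NULL` for single-copy chromosomes (treated as one-chromosome
#'   signals).
#' @param minSize Minimum retained component size (must match the call).
#' @param connectivity Connectivity (must match the call).
#' @return data.frame with zero or more rows: `nucleus_id`, `chromosome`,
#'   `signal_kind` (`one-chromosome`/`two-chromosome`), `component`,
#'   `signal_voxels`, `nucleus_voxels`, `nvp_pct`, `volume_um3`.
#' @export
nuclearVolumeProportion <- function(signal, nucleus, call = NULL,
                                    minSize = 5, connectivity = 26) {
  stopifnot(is(signal, "SignalMask"), is(nucleus, "NucleusMask"))
  nvox <- sum(nucleus@mask)
  if (nvox == 0) stop("empty nucleus mask")
  lab <- labelComponents(signal@mask, connectivity)
  keep <- which(lab$sizes >= minSize)
  empty <- data.frame(nucleus_id = character(), chromosome = character(),
                      signal_kind = character(), component = integer(),
                      signal_voxels = integer(), nucleus_voxels = integer(),
                      nvp_pct = numeric(), volume_um3 = numeric(),
                      stringsAsFactors = FALSE)
  if (!length(keep)) return(empty)
  vx <- prod(signal@spacing)
  row <- function(kind, comp, voxels) data.frame(
    nucleus_id = signal@nucleusId, chromosome = signal@chromosome,
    signal_kind = kind, component = comp, signal_voxels = voxels,
    nucleus_voxels = nvox, nvp_pct = 100 * voxels / nvox,
    volume_um3 = voxels * vx, stringsAsFactors = FALSE)
  verdict <- if (is.null(call)) "single" else call$verdict
  if (verdict == "paired") {
    row("two-chromosome", 1L, sum(lab$sizes[keep]))
  } else if (verdict == "unpaired") {
    do.call(rbind, lapply(seq_along(keep), function(i)
      row("one-chromosome", i, lab$sizes[keep[i]])))
  } else if (verdict == "single") {
    row("one-chromosome", 1L, sum(lab$sizes[keep]))
  } else {
    empty
  }
}

#' Voxel-level recovery of ground-truth territories
#'
#' For a synthetic nucleus, compares every segmented territory mask with
#' its ground-truth voxel set (Jaccard index) and every pairing verdict
#' with the generated state. Only meaningful for records carrying ground
#' truth.
#'
#' @param record A [NucleusRecord-class] with ground truth.
#' @param metrics The [nucleusMetrics()] result for `record`.
#' @return data.frame: `nucleus_id`, `chromosome`, `round`, `jaccard`,
#'   `true_verdict`, `called_verdict`, `verdict_match`.
#' @export
signalRecovery <- function(record, metrics) {
  stopifnot(is(record, "NucleusRecord"))
  gt <- record@groundTruth
  if (!length(gt)) stop("record has no ground truth")
  rows <- lapply(names(gt$territories), function(ch) {
    t <- gt$territories[[ch]]
    tm <- array(FALSE, gt$dims); tm[t$union] <- TRUE
    sig <- metrics$signals[[t$round]][[ch]]
    called <- if (ch %in% metrics$calls$chromosome)
      metrics$calls$verdict[metrics$calls$chromosome == ch] else
      NA_character_
    tv <- if (is.na(t$paired)) NA_character_ else
      if (t$paired) "paired" else "unpaired"
    data.frame(nucleus_id = record@nucleusId, chromosome = ch,
               round = t$round,
               jaccard = jaccard(maskArray(sig), tm),
               true_verdict = tv, called_verdict = called,
               verdict_match = if (is.na(tv)) NA else
                 identical(tv, called),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Run segmentation and all per-nucleus metrics for one nucleus
#'
#' Segments the nucleus and every painted chromosome territory in each
#' hybridization round, classifies homolog pairing for the classifiable
#' chromosomes, computes heterologous association for chromosome pairs
#' imaged in the same round (different fluorochromes), and the nuclear
#' volume proportion of every signal.
#'
#' @param record A [NucleusRecord-class].
#' @param sigma Segmentation pre-smoothing sigma, xy voxels.
#' @param minSize Minimum component size shared by segmentation and
#'   classification, voxels.
#' @param connectivity Voxel connectivity (6, 18 or 26).
#' @return List with data.frames `calls`, `associations`, `nvp`, `nuclei`,
#'   plus `signals` (list of [SignalMask-class]) and `nucleusMasks`.
#' @export
nucleusMetrics <- function(record, sigma = 0.7, minSize = 5,
                           connectivity = 26) {
  stopifnot(is(record, "NucleusRecord"))
  id <- record@nucleusId
  calls <- list(); assoc <- list(); nvp <- list(); nucrows <- list()
  signals <- list(); nucmasks <- list()
  for (rd in names(record@stacks)) {
    st <- record@stacks[[rd]]
    nuc <- segmentNucleus(st, sigma = sigma, connectivity = connectivity,
                          id = id)
    nucmasks[[rd]] <- nuc
    nucrows[[rd]] <- data.frame(
      nucleus_id = id, stage = record@stage, round = rd,
      nucleus_voxels = sum(nuc@mask), volume_um3 = volumeUm3(nuc),
      stringsAsFactors = FALSE)
    chans <- names(st@channelMap)[!is.na(st@channelMap)]
    rd_signals <- list()
    for (ch in chans) {
      chr <- st@channelMap[[ch]]
      sig <- segmentTerritory(st, ch, nuc, sigma = sigma,
                              minSize = minSize,
                              connectivity = connectivity)
      rd_signals[[chr]] <- sig
      if (chr != "Y") {
        cl <- classifyPairing(sig, minSize = minSize,
                              connectivity = connectivity)
        cl$stage <- record@stage
        calls[[paste(rd, chr)]] <- cl
        nv <- nuclearVolumeProportion(sig, nuc, cl, minSize = minSize,
                                      connectivity = connectivity)
      } else {
        nv <- nuclearVolumeProportion(sig, nuc, NULL, minSize = minSize,
                                      connectivity = connectivity)
      }
      if (nrow(nv)) {
        nv$stage <- record@stage; nv$round <- rd
        nvp[[paste(rd, chr)]] <- nv
      }
    }
    chrs <- names(rd_signals)
    if (length(chrs) > 1) {
      prs <- utils::combn(chrs, 2)
      for (p in seq_len(ncol(prs))) {
        ar <- association(rd_signals[[prs[1, p]]], rd_signals[[prs[2, p]]])
        ar$stage <- record@stage
        assoc[[paste(rd, p)]] <- ar
      }
    }
    signals[[rd]] <- rd_signals
  }
  list(calls = if (length(calls)) do.call(rbind, c(calls,
         list(make.row.names = FALSE))) else NULL,
       associations = if (length(assoc)) do.call(rbind, c(assoc,
         list(make.row.names = FALSE))) else NULL,
       nvp = if (length(nvp)) do.call(rbind, c(nvp,
         list(make.row.names = FALSE))) else NULL,
       nuclei = do.call(rbind, c(nucrows, list(make.row.names = FALSE))),
       signals = signals, nucleusMasks = nucmasks)
}
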