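#' Supported cell-stage labels
#'
#' The four spermatogenic intervals plus the somatic lymphocyte baseline.
#' Roman-numeral aliases `I`-`IV` are accepted anywhere a stage label is
#' taken and are normalised to these canonical names.
#'
#' @return Character vector of the five canonical stage labels.
#' @export
#' @examples
#' stageLabels()
stageLabels <- function() {
  c("spermatogonia-early-preleptotene",
    "mid-preleptotene-zygotene",
    "pachytene",
    "round-spermatid",
    "lymphocyte")
}

.stage_aliases <- c(I = "spermatogonia-early-preleptotene",
                    II = "mid-preleptotene-zygotene",
                    III = "pachytene",
                    IV = "round-spermatid",
                    Lym = "lymphocyte")

normalizeStage <- function(stage) {
  stage <- as.character(stage)
  out <- ifelse(stage %in% names(.stage_aliases),
                unname(.stage_aliases[stage]), stage)
  bad <- setdiff(unique(out), stageLabels())
  if (length(bad))
    stop("unknown stage label(s): ", paste(bad, collapse = ", "))
  out
}

#' Mouse karyotype chromosome identifiers
#'
#' @param classifiable Logical; if `TRUE`, drop the single-copy Y
#'   chromosome, leaving the 20 chromosomes whose homolog pairing state can
#'   be classified (autosomes 1-19 plus X).
#' @return Character vector of chromosome identifiers.
#' @export
chromosomeIds <- function(classifiable = FALSE) {
  ids <- c(as.character(1:19), "X", "Y")
  if (classifiable) ids[ids != "Y"] else ids
}

.check_spacing <- function(spacing) {
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    return("voxel spacing must be three strictly positive finite values")
  NULL
}

#' VoxelStack: one multi-channel 3D intensity stack
#'
#' Holds the intensity arrays of one hybridization round for one nucleus.
#' All channels share dimensions `(y, x, z)` and physical voxel spacing.
#' `channelMap` maps channel names (fluorochromes) to chromosome
#' identifiers; the nuclear counterstain channel maps to `NA`.
#'
#' @slot channels Named list of 3D numeric arrays (identical dimensions,
#'   non-negative intensities).
#' @slot spacing Named numeric vector `c(x=, y=, z=)`, micrometres.
#' @slot roundId Character scalar, hybridization round identifier.
#' @slot channelMap Named character vector: channel name -> chromosome id
#'   (`NA` for the counterstain).
#' @export
setClass("VoxelStack",
  representation(channels = "list", spacing = "numeric",
                 roundId = "character", channelMap = "character"),
  validity = function(object) {
    if (!length(object@channels)) return("at least one channel required")
    dims <- lapply(object@channels, dim)
    if (any(vapply(dims, length, 0L) != 3))
      return("all channels must be 3D arrays")
    if (!all(vapply(dims, identical, TRUE, dims[[1]])))
      return("all channels must share identical dimensions")
    if (any(vapply(object@channels, function(a) any(a < 0), TRUE)))
      return("intensities must be non-negative")
    msg <- .check_spacing(object@spacing)
    if (!is.null(msg)) return(msg)
    if (is.null(names(object@channels)) ||
        !setequal(names(object@channels), names(object@channelMap)))
      return("channelMap names must match channel names")
    chr <- object@channelMap[!is.na(object@channelMap)]
    if (anyDuplicated(chr))
      return("chromosome ids must be unique across channels within a round")
    TRUE
  })

#' NucleusMask: binary 3D nucleus segmentation
#'
#' @slot nucleusId Character scalar.
#' @slot mask Logical 3D array in the frame of the source stack.
#' @slot spacing Named numeric vector `c(x=, y=, z=)`, micrometres.
#' @export
setClass("NucleusMask",
  representation(nucleusId = "character", mask = "array",
                 spacing = "numeric"),
  validity = function(object) {
    if (length(dim(object@mask)) != 3) return("mask must be a 3D array")
    if (!is.logical(object@mask)) return("mask must be logical")
    msg <- .check_spacing(object@spacing)
    if (!is.null(msg)) return(msg)
    TRUE
  })

#' SignalMask: binary 3D mask of one chromosome's hybridization signal
#'
#' @slot nucleusId Character scalar.
#' @slot chromosome Chromosome identifier ("1".."19", "X", "Y").
#' @slot roundId Hybridization round the signal was imaged in.
#' @slot mask Logical 3D array, same frame as the source stack.
#' @slot spacing Named numeric vector `c(x=, y=, z=)`, micrometres.
#' @export
setClass("SignalMask",
  representation(nucleusId = "character", chromosome = "character",
                 roundId = "character", mask = "array",
                 spacing = "numeric"),
  validity = function(object) {
    if (length(dim(object@mask)) != 3) return("mask must be a 3D array")
    if (!is.logical(object@mask)) return("mask must be logical")
    msg <- .check_spacing(object@spacing)
    if (!is.null(msg)) return(msg)
    TRUE
  })

#' NucleusRecord: all stacks and metadata for one nucleus
#'
#' @slot nucleusId Character scalar.
#' @slot stage Canonical stage label (see [stageLabels()]).
#' @slot stacks Named list of [VoxelStack-class] objects, one per
#'   hybridization round; all share voxel spacing.
#' @slot groundTruth List with voxel-level ground truth for synthetic
#'   nuclei (see [generateNucleus()]), or an empty list for real data.
#' @export
setClass("NucleusRecord",
  representation(nucleusId = "character", stage = "character",
                 stacks = "list", groundTruth = "list"),
  validity = function(object) {
    if (!object@stage %in% stageLabels())
      return(paste("unknown stage label:", object@stage))
    if (!length(object@stacks)) return("at least one stack required")
    if (any(!vapply(object@stacks, is, TRUE, "VoxelStack")))
      return("stacks must be VoxelStack objects")
    sp <- lapply(object@stacks, function(s) unname(s@spacing))
    if (!all(vapply(sp, function(x) isTRUE(all.equal(x, sp[[1]])), TRUE)))
      return("all stacks of a nucleus must share voxel spacing")
    TRUE
  })
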