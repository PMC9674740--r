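#' @name accessors
#' @title Accessors for TerritoryFISH classes
#' @description Small generic accessors used instead of direct slot access.
#' @param object A TerritoryFISH S4 object.
#' @return `spacing()` the voxel spacing vector; `maskArray()` the logical
#'   3D array of a mask; `voxelCount()` the number of foreground voxels;
#'   `volumeUm3()` the physical volume in cubic micrometres; `nucleusId()`,
#'   `stageLabel()`, `chromosome()` the respective identifiers;
#'   `channelNames()` the channel names of a stack.
NULL

#' @rdname accessors
#' @export
setGeneric("spacing", function(object) standardGeneric("spacing"))
#' @rdname accessors
#' @export
setGeneric("maskArray", function(object) standardGeneric("maskArray"))
#' @rdname accessors
#' @export
setGeneric("voxelCount", function(object) standardGeneric("voxelCount"))
#' @rdname accessors
#' @export
setGeneric("volumeUm3", function(object) standardGeneric("volumeUm3"))
#' @rdname accessors
#' @export
setGeneric("nucleusId", function(object) standardGeneric("nucleusId"))
#' @rdname accessors
#' @export
setGeneric("stageLabel", function(object) standardGeneric("stageLabel"))
#' @rdname accessors
#' @export
setGeneric("chromosome", function(object) standardGeneric("chromosome"))
#' @rdname accessors
#' @export
setGeneric("channelNames", function(object) standardGeneric("channelNames"))

#' @rdname accessors
#' @export
setMethod("spacing", "VoxelStack", function(object) object@spacing)
#' @rdname accessors
#' @export
setMethod("spacing", "NucleusMask", function(object) object@spacing)
#' @rdname accessors
#' @export
setMethod("spacing", "SignalMask", function(object) object@spacing)
#' @rdname accessors
#' @export
setMethod("spacing", "NucleusRecord",
          function(object) object@stacks[[1]]@spacing)

#' @rdname accessors
#' @export
setMethod("maskArray", "NucleusMask", function(object) object@mask)
#' @rdname accessors
#' @export
setMethod("maskArray", "SignalMask", function(object) object@mask)

#' @rdname accessors
#' @export
setMethod("voxelCount", "NucleusMask", function(object) sum(object@mask))
#' @rdname accessors
#' @export
setMethod("voxelCount", "SignalMask", function(object) sum(object@mask))

#' @rdname accessors
#' @export
setMethod("volumeUm3", "NucleusMask",
          function(object) sum(object@mask) * prod(object@spacing))
#' @rdname accessors
#' @export
setMethod("volumeUm3", "SignalMask",
          function(object) sum(object@mask) * prod(object@spacing))

#' @rdname accessors
#' @export
setMethod("nucleusId", "NucleusMask", function(object) object@nucleusId)
#' @rdname accessors
#' @export
setMethod("nucleusId", "SignalMask", function(object) object@nucleusId)
#' @rdname accessors
#' @export
setMethod("nucleusId", "NucleusRecord", function(object) object@nucleusId)

#' @rdname accessors
#' @export
setMethod("stageLabel", "NucleusRecord", function(object) object@stage)

#' @rdname accessors
#' @export
setMethod("chromosome", "SignalMask", function(object) object@chromosome)

#' @rdname accessors
#' @export
setMethod("channelNames", "VoxelStack",
          function(object) names(object@channels))

#' Extract one channel's intensity array from a stack
#'
#' @param stack A [VoxelStack-class].
#' @param channel Channel name, or a chromosome id present in the stack's
#'   channel map.
#' @return 3D numeric array.
#' @export
getChannel <- function(stack, channel) {
  stopifnot(is(stack, "VoxelStack"))
  if (channel %in% names(stack@channels))
    return(stack@channels[[channel]])
  hit <- names(stack@channelMap)[!is.na(stack@channelMap) &
                                 stack@channelMap == channel]
  if (length(hit) == 1) return(stack@channels[[hit]])
  stop("channel '", channel, "' not found in stack (round ",
       stack@roundId, ")")
}

setMethod("show", "VoxelStack", function(object) {
  d <- dim(object@channels[[1]])
  cat("VoxelStack round", object@roundId, ":", length(object@channels),
      "channel(s),", paste(d, collapse = " x "),
      sprintf("voxels, spacing %.3g x %.3g x %.3g um\n",
              object@spacing[["x"]], object@spacing[["y"]],
              object@spacing[["z"]]))
  cm <- object@channelMap
  cat("  channels:", paste(sprintf("%s->%s", names(cm),
      ifelse(is.na(cm), "counterstain", cm)), collapse = ", "), "\n")
})

setMethod("show", "NucleusMask", function(object) {
  cat("NucleusMask", object@nucleusId, ":", sum(object@mask), "voxels (",
      sprintf("%.1f um^3", sum(object@mask) * prod(object@spacing)), ")\n")
})

setMethod("show", "SignalMask", function(object) {
  cat("SignalMask", object@nucleusId, "chr", object@chromosome, "round",
      object@roundId, ":", sum(object@mask), "voxels\n")
})

setMethod("show", "NucleusRecord", function(object) {
  cat("NucleusRecord", object@nucleusId, "(", object@stage, "):",
      length(object@stacks), "round(s)",
      if (length(object@groundTruth)) "with ground truth" else "", "\n")
})
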