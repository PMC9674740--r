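#' Load a packaged observed-data table
#'
#' The package ships three small tables transcribed from the published
#' study they accompany: per-chromosome genomic features of the mouse
#' karyotype (`"features"`: size in Mb, %GC, gene count, NOR presence),
#' per-stage counts of nuclei showing one vs two FISH signals per
#' chromosome (`"pairing_counts"`), and per-chromosome mean nuclear volume
#' proportions of one-chromosome and two-chromosome signals
#' (`"nvp"`). Tables are validated against their structural invariants on
#' every load.
#'
#' @param name One of `"features"`, `"pairing_counts"`, `"nvp"`.
#' @return A data.frame. `features`: `chromosome`, `size_mb`,
#'   `gc_percent`, `gene_density`, `nor`. `pairing_counts`: `stage`,
#'   `chromosome`, `n_two_signal`, `n_one_signal`, `total`,
#'   `single_copy`. `nvp`: `stage`, `chromosome`, `signal_kind`, `n`,
#'   `nvp_pct`.
#' @export
#' @examples
#' f <- loadFixture("features")
#' f[f$chromosome == "1", ]
loadFixture <- function(name = c("features", "pairing_counts", "nvp")) {
  name <- match.arg(name)
  file <- switch(name,
    features = "chromosome_features.csv",
    pairing_counts = "pairing_counts.csv",
    nvp = "nvp_observed.csv")
  path <- system.file("extdata", file, package = "TerritoryFISH",
                      mustWork = TRUE)
  x <- read.csv(path, colClasses = c(chromosome = "character"))
  switch(name,
    features = {
      if (nrow(x) != 21 || !setequal(x$chromosome, chromosomeIds()))
        stop("features table must have exactly the 21 mouse chromosomes")
      if (any(x$size_mb <= 0) ||
          any(x$gc_percent <= 0 | x$gc_percent >= 100))
        stop("features table out of range")
      if (!setequal(x$chromosome[x$nor],
                    c("11", "12", "15", "16", "18", "19")))
        stop("NOR flags do not match the expected chromosome set")
    },
    pairing_counts = {
      if (!all(x$total == x$n_two_signal + x$n_one_signal))
        stop("pairing counts do not add up to the stored totals")
      tab <- table(x$stage, x$chromosome)
      if (!setequal(rownames(tab), stageLabels()[1:4]) || any(tab != 1))
        stop("pairing counts must cover 21 chromosomes in 4 stages")
      if (!all(x$single_copy == (x$chromosome == "Y")))
        stop("single-copy flag must mark exactly the Y chromosome")
    },
    nvp = {
      tab <- table(x$stage, x$chromosome, x$signal_kind)
      if (!setequal(dimnames(tab)[[1]], stageLabels()[1:2]) ||
          !setequal(dimnames(tab)[[3]],
                    c("one-chromosome", "two-chromosome")) ||
          any(tab != 1))
        stop("NVP table must cover 21 chromosomes x 2 kinds x 2 stages")
      if (any(x$nvp_pct <= 0 | x$nvp_pct > 100))
        stop("NVP percentages out of range")
    })
  x
}

.stack_filename <- function(id, round) sprintf("%s_%s.tif", id, round)

#' Write a nucleus record to disk
#'
#' Each hybridization round is written as one multi-page 32-bit float TIFF
#' (pages are the z-sections of each channel in channel order), and the
#' metadata — nucleus id, stage, voxel spacing, per-round dimensions and
#' channel-to-chromosome map — goes to a JSON sidecar, as does the ground
#' truth of synthetic nuclei.
#'
#' @param record A [NucleusRecord-class].
#' @param dir Output directory (created if needed).
#' @param groundTruth Write the ground-truth JSON when the record has one.
#' @return Invisibly, the sidecar metadata path.
#' @export
writeNucleus <- function(record, dir, groundTruth = TRUE) {
  stopifnot(is(record, "NucleusRecord"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- record@nucleusId
  meta <- list(nucleus_id = id, stage = record@stage,
               spacing_um = as.list(spacing(record)), rounds = list())
  for (rd in names(record@stacks)) {
    st <- record@stacks[[rd]]
    d <- dim(st@channels[[1]])
    pages <- list()
    for (ch in names(st@channels)) {
      a <- st@channels[[ch]]
      for (k in seq_len(d[3])) pages[[length(pages) + 1]] <- a[, , k]
    }
    f <- file.path(dir, .stack_filename(id, rd))
    tiff::writeTIFF(pages, f, bits.per.sample = 32L, reduce = FALSE)
    meta$rounds[[rd]] <- list(
      file = basename(f), dim = as.integer(d),
      channels = names(st@channels),
      channel_map = as.list(st@channelMap))
  }
  if (groundTruth && length(record@groundTruth)) {
    gt <- record@groundTruth
    gt$associations <- as.list(gt$associations)
    jsonlite::write_json(gt, file.path(dir, paste0(id, "_truth.json")),
                         auto_unbox = TRUE, digits = NA)
    meta$ground_truth <- paste0(id, "_truth.json")
  }
  mf <- file.path(dir, paste0(id, ".json"))
  jsonlite::write_json(meta, mf, auto_unbox = TRUE, digits = NA)
  invisible(mf)
}

#' Read a nucleus record written by [writeNucleus()]
#'
#' @param dir Directory containing the TIFF stacks and JSON sidecar.
#' @param id Nucleus identifier.
#' @param groundTruth Read the ground-truth JSON if present.
#' @return A [NucleusRecord-class].
#' @export
readNucleus <- function(dir, id, groundTruth = TRUE) {
  mf <- file.path(dir, paste0(id, ".json"))
  if (!file.exists(mf)) stop("metadata file not found: ", mf)
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!meta$stage %in% stageLabels())
    stop("unknown stage label in ", mf, ": ", meta$stage)
  sp <- unlist(meta$spacing_um)[c("x", "y", "z")]
  stacks <- list()
  for (rd in names(meta$rounds)) {
    info <- meta$rounds[[rd]]
    f <- file.path(dir, info$file)
    if (!file.exists(f)) stop("stack file not found: ", f)
    pages <- tiff::readTIFF(f, all = TRUE)
    d <- as.integer(info$dim)
    chans <- unlist(info$channels)
    if (length(pages) != length(chans) * d[3])
      stop("dimension mismatch in ", f, ": expected ",
           length(chans) * d[3], " pages, found ", length(pages))
    if (!all(vapply(pages, function(p) identical(dim(p), d[1:2]), TRUE)))
      stop("dimension mismatch in ", f, ": page size differs from metadata")
    arrs <- list()
    for (i in seq_along(chans)) {
      a <- array(0, d)
      for (k in seq_len(d[3]))
        a[, , k] <- pages[[(i - 1) * d[3] + k]]
      arrs[[chans[i]]] <- a
    }
    cm <- meta$rounds[[rd]]$channel_map
    cmap <- vapply(cm, function(v)
      if (is.null(v) || is.na(v) || !nzchar(v)) NA_character_
      else as.character(v), "")
    names(cmap) <- names(cm)
    missing_ch <- setdiff(names(cmap), names(arrs))
    if (length(missing_ch))
      stop("missing channel(s) in ", f, ": ",
           paste(missing_ch, collapse = ", "))
    stacks[[rd]] <- new("VoxelStack", channels = arrs, spacing = sp,
                        roundId = rd, channelMap = cmap)
  }
  gt <- list()
  if (groundTruth && !is.null(meta$ground_truth)) {
    gtf <- file.path(dir, meta$ground_truth)
    if (file.exists(gtf)) {
      gt <- jsonlite::read_json(gtf, simplifyVector = TRUE)
      gt$dims <- as.integer(gt$dims)
      gt$nucleus <- as.integer(gt$nucleus)
      gt$territories <- lapply(gt$territories, function(t) {
        t$copies <- lapply(t$copies, as.integer)
        t$union <- as.integer(t$union)
        t
      })
      gt$associations <- as.data.frame(gt$associations)
    }
  }
  new("NucleusRecord", nucleusId = meta$nucleus_id, stage = meta$stage,
      stacks = stacks, groundTruth = gt)
}

#' Write a binary mask as an 8-bit multi-page TIFF (0/255)
#'
#' @param mask Logical 3D array, or a [SignalMask-class] /
#'   [NucleusMask-class].
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
writeMask <- function(mask, file) {
  if (is(mask, "SignalMask") || is(mask, "NucleusMask"))
    mask <- maskArray(mask)
  stopifnot(is.logical(mask), length(dim(mask)) == 3)
  pages <- lapply(seq_len(dim(mask)[3]),
                  function(k) mask[, , k] * 1.0)
  tiff::writeTIFF(pages, file, bits.per.sample = 8L)
  invisible(file)
}

#' Read a binary mask written by [writeMask()]
#'
#' @param file TIFF path.
#' @return Logical 3D array.
#' @export
readMask <- function(file) {
  pages <- tiff::readTIFF(file, all = TRUE)
  d <- c(dim(pages[[1]]), length(pages))
  out <- array(FALSE, d)
  for (k in seq_along(pages)) out[, , k] <- pages[[k]] > 0.5
  out
}
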