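# Independent oracles and small fixtures used across the test files.

# Brute-force connected components by iterative minimum-label propagation
# over shifted copies of the array. Deliberately independent of the
# package's stack-based labelling: converges to the same partition by a
# different route.
oracle_label <- function(mask, connectivity) {
  d <- dim(mask)
  lab <- array(seq_along(mask), d)
  lab[!mask] <- 0L
  offs <- expand.grid(dy = -1:1, dx = -1:1, dz = -1:1)
  s <- abs(offs$dy) + abs(offs$dx) + abs(offs$dz)
  keep <- s > 0 & (connectivity == 26 |
                   (connectivity == 18 & s <= 2) |
                   (connectivity == 6 & s <= 1))
  offs <- offs[keep, ]
  shift0 <- function(a, dy, dx, dz) {
    out <- array(0L, d)
    ys <- seq(max(1, 1 + dy), min(d[1], d[1] + dy))
    xs <- seq(max(1, 1 + dx), min(d[2], d[2] + dx))
    zs <- seq(max(1, 1 + dz), min(d[3], d[3] + dz))
    out[ys, xs, zs] <- a[ys - dy, xs - dx, zs - dz]
    out
  }
  repeat {
    nxt <- lab
    for (i in seq_len(nrow(offs))) {
      sh <- shift0(lab, offs$dy[i], offs$dx[i], offs$dz[i])
      upd <- mask & sh > 0L & sh < nxt
      nxt[upd] <- sh[upd]
    }
    if (identical(nxt, lab)) break
    lab <- nxt
  }
  lab
}

# Canonical renumbering of a labelling restricted to foreground voxels,
# in voxel-index order, so two labelings can be compared as partitions.
canonical_labels <- function(lab, mask) {
  v <- lab[mask]
  match(v, unique(v))
}

expect_same_partition <- function(lab_a, lab_b, mask) {
  expect_identical(canonical_labels(lab_a, mask),
                   canonical_labels(lab_b, mask))
}

# A small single-region preset for fast population-level tests: three
# chromosomes, one round, uniform pairing probability and territory size.
mini_preset <- function(p = 0.5, nvp_one = 1.1, nvp_two = 1.62 * nvp_one,
                        chroms = c("1", "2", "3")) {
  layout <- data.frame(region = 1L, round = "r1",
                       channel = c("DEAC", "FITC", "TexasRed")[
                         seq_along(chroms)],
                       chromosome = chroms, stringsAsFactors = FALSE)
  structure(list(
    stage = "spermatogonia-early-preleptotene", chromosomes = chroms,
    copies = setNames(rep(2L, length(chroms)), chroms),
    pairingProb = setNames(rep(p, length(chroms)), chroms),
    nvpOne = setNames(rep(nvp_one, length(chroms)), chroms),
    nvpTwo = setNames(rep(nvp_two, length(chroms)), chroms),
    layout = layout), class = "StagePreset")
}

# Small nuclei keep the unit tests fast.
small_geometry <- list(semiaxesUm = c(1.8, 1.6, 1.2))

truth_mask <- function(record, what, chromosome = NULL) {
  gt <- record@groundTruth
  m <- array(FALSE, gt$dims)
  if (identical(what, "nucleus")) m[gt$nucleus] <- TRUE
  else m[gt$territories[[chromosome]]$union] <- TRUE
  m
}

random_mask <- function(d = c(10, 10, 10), p = 0.5) {
  array(runif(prod(d)) < p, d)
}
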