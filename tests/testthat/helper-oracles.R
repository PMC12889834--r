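# Independent oracles used across the suite.

# Brute-force enumeration of exposed droplet-surface faces adjacent to the
# mitochondrial mask: walks the coordinate list of LD voxels directly (the
# production code instead shifts whole logical arrays). A face between LD
# voxel a and its 6-neighbour b counts when b is outside the LD mask and a
# mito voxel lies within `dist` steps beyond a along that axis.
oracle_contact <- function(ld, mito, voxel_size = c(0.329, 0.063, 0.063),
                           dist = 1L) {
  d <- dim(ld)
  face_area <- c(voxel_size[2] * voxel_size[3],
                 voxel_size[1] * voxel_size[3],
                 voxel_size[1] * voxel_size[2])
  idx <- which(ld)
  n_faces <- integer(3)
  if (length(idx)) {
    coords <- arrayInd(idx, d)
    dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1))
    for (i in seq_len(nrow(dirs))) {
      dv <- dirs[i, ]
      axis <- which(dv != 0)
      nb <- sweep(coords, 2, dv, `+`)
      inside <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
        nb[, 2] >= 1 & nb[, 2] <= d[2] & nb[, 3] >= 1 & nb[, 3] <= d[3]
      exposed <- !inside   # border faces are exposed but can't touch mito
      exposed[inside] <- !ld[nb[inside, , drop = FALSE]]
      touches <- rep(FALSE, nrow(coords))
      for (k in seq_len(dist)) {
        nk <- sweep(coords, 2, dv * k, `+`)
        ok <- nk[, 1] >= 1 & nk[, 1] <= d[1] &
          nk[, 2] >= 1 & nk[, 2] <= d[2] & nk[, 3] >= 1 & nk[, 3] <= d[3]
        hit <- rep(FALSE, nrow(coords))
        hit[ok] <- mito[nk[ok, , drop = FALSE]]
        touches <- touches | hit
      }
      n_faces[axis] <- n_faces[axis] + sum(exposed & touches)
    }
  }
  if (sum(ld) == 0L || sum(mito) == 0L) n_faces <- integer(3)
  list(n_faces = sum(n_faces),
       area_um2 = sum(n_faces * face_area))
}

random_mask <- function(dims, p = 0.2) {
  array(stats::runif(prod(dims)) < p, dims)
}

# Random small mask pair for the oracle-equivalence properties.
random_mask_pair <- function(max_side = 16L, p_range = c(0.05, 0.4)) {
  dims <- sample(3:max_side, 3, replace = TRUE)
  list(dims = dims,
       ld = random_mask(dims, stats::runif(1, p_range[1], p_range[2])),
       mito = random_mask(dims, stats::runif(1, p_range[1], p_range[2])))
}
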