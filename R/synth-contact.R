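# Synthetic two-channel 3D volumes: tubular mitochondria (capsules along
# random two-segment polylines) plus spherical lipid droplets placed either
# touching a tube (surface gap 0) or separated by at least gap_um. Ground
# truth (noiseless voxel masks and their face-contact metrics) is recorded
# before PSF blur and shot noise are applied.

#' Configuration for a synthetic contact scene
#'
#' Defaults give a 5.3 x 8.1 x 8.1 um SIM-scale volume (16 z-planes at
#' 0.329 um, 0.063 um lateral pitch) holding a handful of mitochondrial
#' tubules and 16 lipid droplets of ~0.3 um radius — a realistic droplet
#' load for one macrophage field. `target_contact_fraction` of the droplets
#' are planted touching a tubule (surface gap exactly 0); the rest sit at
#' least `gap_um` away from every tubule surface.
#'
#' @param volume_shape `(z, y, x)` voxel counts.
#' @param voxel_size `(z, y, x)` voxel sizes in um.
#' @param n_droplets Number of droplets.
#' @param droplet_radius_um,droplet_radius_sd_um Droplet radius mean and sd.
#' @param n_mito_tubes Number of tubules.
#' @param tube_radius_um Tubule radius.
#' @param tube_length_um,tube_length_sd_um Tubule length mean and sd.
#' @param target_contact_fraction Fraction of droplets planted in contact
#'   (exactly `round(n_droplets * target_contact_fraction)` droplets).
#' @param gap_um Minimum tubule-surface separation of non-contacting
#'   droplets.
#' @param psf_sigma_um Gaussian PSF sigma (0 disables blur).
#' @param background Background photon level.
#' @param photon_scale Object photon amplitude above background.
#' @param poisson_noise Apply Poisson shot noise (`FALSE` gives the
#'   noiseless expectation image).
#' @param seed RNG seed.
#' @return A validated `contact_scene_config` list.
#' @export
contact_scene_config <- function(volume_shape = c(16L, 128L, 128L),
                                 voxel_size = default_voxel_size(),
                                 n_droplets = 16L,
                                 droplet_radius_um = 0.30,
                                 droplet_radius_sd_um = 0.03,
                                 n_mito_tubes = 5L,
                                 tube_radius_um = 0.15,
                                 tube_length_um = 3.0,
                                 tube_length_sd_um = 0.5,
                                 target_contact_fraction = 0.3,
                                 gap_um = 0.5,
                                 psf_sigma_um = 0.03,
                                 background = 20,
                                 photon_scale = 200,
                                 poisson_noise = TRUE,
                                 seed = 1L) {
  cfg <- list(volume_shape = as.integer(volume_shape),
              voxel_size = unname(as.numeric(voxel_size)),
              n_droplets = as.integer(n_droplets),
              droplet_radius_um = droplet_radius_um,
              droplet_radius_sd_um = droplet_radius_sd_um,
              n_mito_tubes = as.integer(n_mito_tubes),
              tube_radius_um = tube_radius_um,
              tube_length_um = tube_length_um,
              tube_length_sd_um = tube_length_sd_um,
              target_contact_fraction = target_contact_fraction,
              gap_um = gap_um, psf_sigma_um = psf_sigma_um,
              background = background, photon_scale = photon_scale,
              poisson_noise = isTRUE(poisson_noise), seed = as.integer(seed))
  if (cfg$target_contact_fraction < 0 || cfg$target_contact_fraction > 1) {
    stop("target_contact_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$droplet_radius_um <= 0 || cfg$tube_radius_um <= 0 ||
      cfg$tube_length_um <= 0) {
    stop("radii and lengths must be positive", call. = FALSE)
  }
  if (cfg$gap_um < 0 || cfg$psf_sigma_um < 0) {
    stop("gap_um and psf_sigma_um must be non-negative", call. = FALSE)
  }
  if (any(cfg$volume_shape < 1L) || any(cfg$voxel_size <= 0)) {
    stop("volume_shape and voxel_size must be positive", call. = FALSE)
  }
  cfg
}

# Distance from points P (n x 3 matrix, physical um) to segment AB.
dist_point_segment <- function(P, A, B) {
  AB <- B - A
  len2 <- sum(AB^2)
  if (len2 == 0) return(sqrt(rowSums(sweep(P, 2, A)^2)))
  t_proj <- pmin(pmax((sweep(P, 2, A) %*% AB) / len2, 0), 1)
  proj <- cbind(A[1] + t_proj * AB[1], A[2] + t_proj * AB[2],
                A[3] + t_proj * AB[3])
  sqrt(rowSums((P - proj)^2))
}

dist_to_segments <- function(P, segments) {
  d <- rep(Inf, nrow(P))
  for (s in segments) d <- pmin(d, dist_point_segment(P, s$A, s$B))
  d
}

# Voxelize "distance to any segment <= radius" within per-segment bounding
# boxes. centers: list(z=, y=, x=) of voxel-center coordinates (um).
voxelize_segments <- function(segments, radius, shape, centers) {
  mask <- array(FALSE, shape)
  for (s in segments) {
    lo <- pmin(s$A, s$B) - radius; hi <- pmax(s$A, s$B) + radius
    iz <- which(centers$z >= lo[1] & centers$z <= hi[1])
    iy <- which(centers$y >= lo[2] & centers$y <= hi[2])
    ix <- which(centers$x >= lo[3] & centers$x <= hi[3])
    if (!length(iz) || !length(iy) || !length(ix)) next
    g <- expand.grid(z = centers$z[iz], y = centers$y[iy], x = centers$x[ix])
    inside <- dist_point_segment(as.matrix(g), s$A, s$B) <= radius
    sub <- mask[iz, iy, ix, drop = FALSE]
    sub[array(inside, dim(sub))] <- TRUE
    mask[iz, iy, ix] <- sub
  }
  mask
}

voxelize_sphere <- function(mask, center, radius, centers) {
  iz <- which(abs(centers$z - center[1]) <= radius)
  iy <- which(abs(centers$y - center[2]) <= radius)
  ix <- which(abs(centers$x - center[3]) <= radius)
  if (!length(iz) || !length(iy) || !length(ix)) return(mask)
  g <- expand.grid(z = centers$z[iz], y = centers$y[iy], x = centers$x[ix])
  inside <- rowSums(sweep(as.matrix(g), 2, center)^2) <= radius^2
  sub <- mask[iz, iy, ix, drop = FALSE]
  sub[array(inside, dim(sub))] <- TRUE
  mask[iz, iy, ix] <- sub
  mask
}

# Random unit vector perpendicular to `v` whose z-component is moderate
# (contacts are planted mostly laterally, where the voxel grid resolves
# the interface; |u_z| capped at 0.7).
perp_direction <- function(v) {
  for (i in 1:50) {
    r <- stats::rnorm(3)
    u <- r - sum(r * v) * v
    n <- sqrt(sum(u^2))
    if (n < 1e-9) next
    u <- u / n
    if (abs(u[1]) <= 0.7) return(u)
  }
  u
}

#' Synthesize a two-channel 3D contact scene
#'
#' Renders tubular mitochondria and spherical lipid droplets as voxel
#' masks, records ground truth (the noiseless masks and their voxel-face
#' contact metrics via [contact_area()]), then produces the two intensity
#' channels: `photon_scale x mask` blurred by an anisotropic Gaussian PSF,
#' plus `background`, with optional Poisson shot noise. All droplet radii
#' are drawn first and contacting droplets are placed before non-contacting
#' ones, so scenes differing only in `gap_um` share identical contacting
#' geometry under the same seed.
#'
#' @param cfg A [contact_scene_config()].
#' @return List of class `contact_scene`: `mito`, `ld`
#'   ([volume_image()]s), `truth` (masks as [binary_mask3d()], per-droplet
#'   tibble, `contact` metrics row), and `config`.
#' @export
make_contact_volume <- function(cfg = contact_scene_config()) {
  with_seed(cfg$seed, {
    shape <- cfg$volume_shape
    vs <- cfg$voxel_size
    extent <- shape * vs
    centers <- list(z = (seq_len(shape[1]) - 0.5) * vs[1],
                    y = (seq_len(shape[2]) - 0.5) * vs[2],
                    x = (seq_len(shape[3]) - 0.5) * vs[3])
    # --- mitochondrial tubules: two-segment polylines ---
    segments <- list()
    margin_t <- cfg$tube_radius_um + 0.1
    for (i in seq_len(cfg$n_mito_tubes)) {
      P0 <- c(stats::runif(1, margin_t, extent[1] - margin_t),
              stats::runif(1, margin_t, extent[2] - margin_t),
              stats::runif(1, margin_t, extent[3] - margin_t))
      phi <- stats::runif(1, 0, 2 * pi)
      dz <- stats::runif(1, -0.2, 0.2)
      dir1 <- c(dz, sin(phi), cos(phi))
      dir1 <- dir1 / sqrt(sum(dir1^2))
      len <- max(cfg$tube_length_um +
                   stats::rnorm(1, 0, cfg$tube_length_sd_um), 0.5)
      P1 <- P0 + dir1 * len / 2
      kink <- phi + stats::runif(1, -0.45, 0.45)
      dir2 <- c(dz, sin(kink), cos(kink))
      dir2 <- dir2 / sqrt(sum(dir2^2))
      P2 <- P1 + dir2 * len / 2
      segments <- c(segments, list(list(A = P0, B = P1),
                                   list(A = P1, B = P2)))
    }
    # --- droplets: radii first, then contacting, then separated ---
    n <- cfg$n_droplets
    radii <- if (n > 0) pmax(stats::rnorm(n, cfg$droplet_radius_um,
                                          cfg$droplet_radius_sd_um),
                             cfg$droplet_radius_um / 3) else numeric()
    n_contact <- round(n * cfg$target_contact_fraction)
    droplets <- vector("list", n)
    placed_centers <- matrix(numeric(), ncol = 3, nrow = 0)
    placed_radii <- numeric()
    budget <- 400L * max(n, 1L)
    place_ok <- function(C, r, min_tube_clearance) {
      if (any(C < r + 0.05) || any(C > extent - r - 0.05)) return(FALSE)
      dmin <- if (length(segments)) min(dist_to_segments(rbind(C), segments))
      else Inf
      if (dmin - cfg$tube_radius_um - r < min_tube_clearance) return(FALSE)
      if (nrow(placed_centers) > 0) {
        sep <- sqrt(rowSums(sweep(placed_centers, 2, C)^2))
        if (any(sep < placed_radii + r + 0.05)) return(FALSE)
      }
      TRUE
    }
    for (i in seq_len(n)) {
      contacting <- i <= n_contact
      done <- FALSE
      while (!done && budget > 0L) {
        budget <- budget - 1L
        if (contacting) {
          if (length(segments) == 0L) {
            stop("cannot plant contacting droplets without tubules",
                 call. = FALSE)
          }
          s <- segments[[sample.int(length(segments), 1)]]
          t_pos <- stats::runif(1)
          Q <- s$A + t_pos * (s$B - s$A)
          axis <- (s$B - s$A) / sqrt(sum((s$B - s$A)^2))
          u <- perp_direction(axis)
          C <- Q + u * (cfg$tube_radius_um + radii[i])
          # surface gap exactly 0 to this tubule; forbid burying in others
          ok <- all(C > radii[i] + 0.05) && all(C < extent - radii[i] - 0.05)
          if (ok && nrow(placed_centers) > 0) {
            sep <- sqrt(rowSums(sweep(placed_centers, 2, C)^2))
            ok <- all(sep >= placed_radii + radii[i] + 0.05)
          }
        } else {
          C <- c(stats::runif(1, 0, extent[1]), stats::runif(1, 0, extent[2]),
                 stats::runif(1, 0, extent[3]))
          ok <- place_ok(C, radii[i], cfg$gap_um)
        }
        if (ok) {
          placed_centers <- rbind(placed_centers, C)
          placed_radii <- c(placed_radii, radii[i])
          droplets[[i]] <- tibble::tibble(
            droplet = i, z = C[1], y = C[2], x = C[3],
            radius_um = radii[i], contacting = contacting)
          done <- TRUE
        }
      }
      if (!done) {
        stop(sprintf("droplet placement failed: placed %d of %d (%d contacting requested); enlarge the volume",
                     i - 1L, n, n_contact), call. = FALSE)
      }
    }
    droplets <- dplyr::bind_rows(droplets)
    # --- voxelization ---
    mito_mask <- voxelize_segments(segments, cfg$tube_radius_um, shape,
                                   centers)
    ld_mask <- array(FALSE, shape)
    for (i in seq_len(n)) {
      ld_mask <- voxelize_sphere(ld_mask, unlist(droplets[i, c("z", "y", "x")]),
                                 droplets$radius_um[i], centers)
    }
    mito_bm <- binary_mask3d(mito_mask, vs)
    ld_bm <- binary_mask3d(ld_mask, vs)
    truth_contact <- contact_area(ld_bm, mito_bm, 1L, source = "ground_truth")
    # --- render channels ---
    render <- function(mask) {
      sig <- cfg$photon_scale * (mask * 1)
      if (cfg$psf_sigma_um > 0) {
        sig <- gaussian_blur3d(sig, cfg$psf_sigma_um / vs)
      }
      sig <- sig + cfg$background
      if (cfg$poisson_noise) {
        sig <- array(stats::rpois(length(sig), pmax(sig, 0)), dim(sig))
      }
      volume_image(sig, vs)
    }
    structure(list(mito = render(mito_mask), ld = render(ld_mask),
                   truth = list(mito_mask = mito_bm, ld_mask = ld_bm,
                                droplets = droplets,
                                contact = truth_contact),
                   config = cfg),
              class = "contact_scene")
  })
}
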