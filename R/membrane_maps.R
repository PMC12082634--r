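# Local membrane geometry and volumetric densities.

#' Local membrane thickness map
#'
#' Thickness is the local interleaflet distance of the headgroup
#' (phosphate) beads: per xy cell, the mean z of upper-leaflet heads
#' minus the mean z of lower-leaflet heads, accumulated over frames.
#' Cells sampled by only one leaflet are undefined (`NA`), not zero.
#'
#' @param traj a [trajectory()].
#' @param lipids a [lipid_set()].
#' @param leaflets a `leaflet_series` from [assign_leaflets()]; computed
#'   with defaults when `NULL`.
#' @param spacing xy grid spacing (nm).
#' @return object of class `"thickness_map"`: cell-centre vectors `x`,
#'   `y`, matrix `thickness` (nm, `NA` where undefined) and matrix
#'   `count` (head observations per cell).
#' @export
thickness_map <- function(traj, lipids, leaflets = NULL, spacing = 0.2) {
  if (is.null(leaflets)) leaflets <- assign_leaflets(traj, lipids)
  lx <- mean(traj$box[, 1]); ly <- mean(traj$box[, 2])
  nx <- max(1L, round(lx / spacing)); ny <- max(1L, round(ly / spacing))
  nf <- n_frames(traj)
  hx <- traj$coords[lipids$head, 1, , drop = FALSE][, 1, ] %% lx
  hy <- traj$coords[lipids$head, 2, , drop = FALSE][, 1, ] %% ly
  hz <- traj$coords[lipids$head, 3, , drop = FALSE][, 1, ]
  ix <- pmin(floor(hx / lx * nx) + 1L, nx)
  iy <- pmin(floor(hy / ly * ny) + 1L, ny)
  cell <- (iy - 1L) * nx + ix
  up <- leaflets$assigned > 0
  sum_u <- rowsum(as.numeric(hz[up]), cell[up])
  n_u <- rowsum(rep(1, sum(up)), cell[up])
  sum_l <- rowsum(as.numeric(hz[!up]), cell[!up])
  n_l <- rowsum(rep(1, sum(!up)), cell[!up])
  mean_u <- rep(NA_real_, nx * ny); mean_l <- rep(NA_real_, nx * ny)
  cnt <- numeric(nx * ny)
  iu <- as.integer(rownames(sum_u)); il <- as.integer(rownames(sum_l))
  mean_u[iu] <- sum_u / n_u
  mean_l[il] <- sum_l / n_l
  cnt[iu] <- cnt[iu] + n_u
  cnt[il] <- cnt[il] + n_l
  thick <- mean_u - mean_l
  thick[!is.na(thick) & thick <= 0] <- NA_real_
  structure(list(x = (seq_len(nx) - 0.5) * lx / nx,
                 y = (seq_len(ny) - 0.5) * ly / ny,
                 thickness = matrix(thick, nx, ny),
                 count = matrix(cnt, nx, ny),
                 spacing = c(lx / nx, ly / ny)),
            class = "thickness_map")
}

#' Classify lipids by proximity to protein sites
#'
#' Per lipid and frame, the minimum 3D head-to-protein-bead distance
#' decides the class: within `near_cutoff` of a site, the lipid is near
#' that site (nearest site wins); at least `bulk_exclusion` from every
#' site, it is bulk; otherwise intermediate. The three classes
#' partition every frame exhaustively.
#'
#' @param traj,lipids,sites as elsewhere.
#' @param near_cutoff,bulk_exclusion distances in nm,
#'   `near_cutoff < bulk_exclusion`.
#' @return character matrix `n_lipids x n_frames` with entries
#'   `"near-<site>"`, `"bulk"` or `"intermediate"`.
#' @export
classify_lipid_environment <- function(traj, lipids, sites,
                                       near_cutoff = 2.0,
                                       bulk_exclusion = 3.0) {
  stopifnot(near_cutoff < bulk_exclusion)
  n_lip <- nrow(lipids); nf <- n_frames(traj)
  labels <- matrix("bulk", n_lip, nf)
  if (length(sites$sites) == 0) return(labels)
  site_names <- sort(names(sites$sites))
  for (f in seq_len(nf)) {
    h <- matrix(traj$coords[lipids$head, , f], ncol = 3)
    dmin <- matrix(Inf, n_lip, length(site_names))
    for (si in seq_along(site_names)) {
      b <- matrix(traj$coords[sites$sites[[site_names[si]]], , f], ncol = 3)
      for (bi in seq_len(nrow(b))) {
        d2 <- (h[, 1] - b[bi, 1])^2 + (h[, 2] - b[bi, 2])^2 +
          (h[, 3] - b[bi, 3])^2
        dmin[, si] <- pmin(dmin[, si], d2)
      }
    }
    dmin <- sqrt(dmin)
    best <- max.col(-dmin, ties.method = "first")
    dbest <- dmin[cbind(seq_len(n_lip), best)]
    lab <- rep("intermediate", n_lip)
    lab[dbest <= near_cutoff] <- paste0("near-", site_names[best])[dbest <= near_cutoff]
    lab[apply(dmin, 1, min) >= bulk_exclusion] <- "bulk"
    labels[, f] <- lab
  }
  labels
}

#' Time-averaged 3D density map of selected beads
#'
#' Coordinates are expressed in the reference-group frame (per-frame
#' centroid subtracted; `NULL` keeps the box frame), histogrammed into
#' cubic voxels, normalized by frames x voxel volume, and averaged
#' across replicas. The bookkeeping identity
#' `sum(density) * voxel_volume * n_frames = total observations` holds
#' exactly per replica.
#'
#' @param trajs a [trajectory()] or list of replica trajectories.
#' @param indices bead indices to map (same topology in all replicas).
#' @param ref_indices reference-group indices or `NULL`.
#' @param voxel voxel edge (nm), > 0.01.
#' @return object of class `"density_map3d"`: grids `x`, `y`, `z`
#'   (voxel centres), 3D `density` array (1/nm^3), `voxel`, `n_frames`,
#'   `n_replicas`, `n_obs`.
#' @export
volumetric_density <- function(trajs, indices, ref_indices = NULL,
                               voxel = 0.2) {
  if (voxel <= 0.01) stop("degenerate voxel size")
  if (inherits(trajs, "traj")) trajs <- list(trajs)
  box <- trajs[[1]]$box[1, ]
  nx <- max(1L, round(box[1] / voxel))
  ny <- max(1L, round(box[2] / voxel))
  nz <- max(1L, round(box[3] / voxel))
  vx <- box[1] / nx; vy <- box[2] / ny; vz <- box[3] / nz
  dens <- array(0, dim = c(nx, ny, nz))
  tot_frames <- 0L; tot_obs <- 0
  for (traj in trajs) {
    counts <- array(0, dim = c(nx, ny, nz))
    nf <- n_frames(traj)
    for (f in seq_len(nf)) {
      p <- matrix(traj$coords[indices, , f], ncol = 3)
      if (!is.null(ref_indices)) {
        ref <- colMeans(matrix(traj$coords[ref_indices, , f], ncol = 3))
        # keep the reference centred in the box so all wrapped
        # observations stay inside the grid
        p <- sweep(p, 2, ref - box / 2)
      }
      ix <- pmin(floor((p[, 1] %% box[1]) / vx) + 1L, nx)
      iy <- pmin(floor((p[, 2] %% box[2]) / vy) + 1L, ny)
      iz <- pmin(floor((p[, 3] %% box[3]) / vz) + 1L, nz)
      lin <- (iz - 1L) * nx * ny + (iy - 1L) * nx + ix
      tab <- tabulate(lin, nbins = nx * ny * nz)
      counts <- counts + array(tab, dim = c(nx, ny, nz))
      tot_obs <- tot_obs + nrow(p)
    }
    dens <- dens + counts / (nf * vx * vy * vz)
    tot_frames <- tot_frames + nf
  }
  dens <- dens / length(trajs)
  structure(list(x = (seq_len(nx) - 0.5) * vx,
                 y = (seq_len(ny) - 0.5) * vy,
                 z = (seq_len(nz) - 0.5) * vz,
                 density = dens, voxel = c(vx, vy, vz),
                 n_frames = tot_frames, n_replicas = length(trajs),
                 n_obs = tot_obs),
            class = "density_map3d")
}

# 26-connected component labelling by iterative label propagation
.label_components_26 <- function(mask) {
  dims <- dim(mask)
  labels <- array(0L, dims)
  labels[mask] <- seq_len(sum(mask))
  idx <- array(seq_len(prod(dims)), dims)
  shifts <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  shifts <- shifts[!(shifts$dx == 0 & shifts$dy == 0 & shifts$dz == 0), ]
  repeat {
    changed <- FALSE
    for (s in seq_len(nrow(shifts))) {
      dx <- shifts$dx[s]; dy <- shifts$dy[s]; dz <- shifts$dz[s]
      xs <- seq_len(dims[1]); ys <- seq_len(dims[2]); zs <- seq_len(dims[3])
      xs_to <- xs[xs + dx >= 1 & xs + dx <= dims[1]]
      ys_to <- ys[ys + dy >= 1 & ys + dy <= dims[2]]
      zs_to <- zs[zs + dz >= 1 & zs + dz <= dims[3]]
      if (!length(xs_to) || !length(ys_to) || !length(zs_to)) next
      a <- labels[xs_to, ys_to, zs_to, drop = FALSE]
      b <- labels[xs_to + dx, ys_to + dy, zs_to + dz, drop = FALSE]
      upd <- a > 0 & b > 0 & b < a
      if (any(upd)) {
        a[upd] <- b[upd]
        labels[xs_to, ys_to, zs_to] <- a
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  labels
}

#' Pathway continuity of a volumetric density map
#'
#' Thresholds the density, labels 26-connected components of the
#' above-threshold voxels, and declares the pathway continuous when a
#' single component touches both leaflet planes — the signature of an
#' uninterrupted headgroup density bridging the two leaflets.
#'
#' @param map a `density_map3d`.
#' @param z_planes z positions (map frame, nm) of the two leaflet
#'   planes.
#' @param threshold density threshold (> 0), e.g. 10% of the bulk
#'   headgroup plateau.
#' @return list: `continuous` (logical), `threshold`, `n_components`,
#'   `component_sizes`, and `bridging_component` (label or `NA`).
#' @export
pathway_continuity <- function(map, z_planes, threshold) {
  if (threshold <= 0) stop("threshold must be > 0")
  if (min(z_planes) < min(map$z) || max(z_planes) > max(map$z)) {
    stop("leaflet planes outside the map z extent")
  }
  mask <- map$density >= threshold
  labels <- .label_components_26(mask)
  iz1 <- which.min(abs(map$z - min(z_planes)))
  iz2 <- which.min(abs(map$z - max(z_planes)))
  l1 <- unique(as.vector(labels[, , iz1])); l1 <- l1[l1 > 0]
  l2 <- unique(as.vector(labels[, , iz2])); l2 <- l2[l2 > 0]
  bridging <- intersect(l1, l2)
  sizes <- table(labels[labels > 0])
  list(continuous = length(bridging) > 0,
       threshold = threshold,
       n_components = length(sizes),
       component_sizes = sort(as.integer(sizes), decreasing = TRUE),
       bridging_component = if (length(bridging) > 0) bridging[1] else NA_integer_)
}
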