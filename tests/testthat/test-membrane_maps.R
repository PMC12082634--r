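test_that("a flat synthetic bilayer maps to homogeneous 4 nm thickness", {
  g <- small_system(rates = list(POPC = c(bulk = 0)), n_frames = 200,
                    n_per_leaflet = c(POPC = 200), seed = 9)
  tm <- thickness_map(g$traj, g$lipids, spacing = 3.0)  # coarse cells, high counts
  vals <- tm$thickness[!is.na(tm$thickness)]
  expect_gt(length(vals), 0)
  # leaflet planes at +/- 2 nm -> thickness 4 nm; per-cell SE is
  # sigma_z * sqrt(1/n_up + 1/n_low) ~ 2 sigma_z / sqrt(count)
  se_cell <- 2 * 0.3 / sqrt(tm$count[!is.na(tm$thickness)])
  expect_true(all(abs(vals - 4.0) < 3 * se_cell))
  # spatial homogeneity: every defined cell within 3 SE of the global mean
  expect_true(all(abs(vals - mean(vals)) < 3 * se_cell))
})

test_that("sinusoidal leaflet modulation is recovered by the thickness map", {
  set.seed(10)
  n_lip <- 4000
  lx <- 16
  x <- runif(n_lip, 0, lx); y <- runif(n_lip, 0, 8)
  upper <- seq_len(n_lip) <= n_lip / 2
  amp <- 0.5
  zu <- 8 + amp * sin(2 * pi * x / lx)
  zl <- 4 - amp * sin(2 * pi * x / lx)
  coords <- array(NA_real_, c(2 * n_lip, 3, 1))
  head_idx <- seq_len(n_lip) * 2 - 1
  coords[head_idx, 1, 1] <- x
  coords[head_idx, 2, 1] <- y
  coords[head_idx, 3, 1] <- ifelse(upper, zu, zl)
  coords[head_idx + 1, , 1] <- coords[head_idx, , 1]
  coords[head_idx + 1, 3, 1] <- ifelse(upper, zu - 3, zl + 3)
  traj <- trajectory(0, coords, c(lx, 8, 12),
                     data.frame(name = rep(c("PO4", "C4B"), n_lip),
                                resname = "POPC",
                                resid = rep(seq_len(n_lip), each = 2)))
  lipids <- lipid_set(seq_len(n_lip), "POPC", head_idx, head_idx + 1)
  tm <- thickness_map(traj, lipids, spacing = 2.0)
  # cell-averaged expected thickness 4 + 2 amp sin(2 pi x / L)
  for (ix in seq_along(tm$x)) {
    cells <- tm$thickness[ix, ]
    pred <- 4 + 2 * amp * mean(sin(2 * pi *
      (tm$x[ix] + seq(-1, 1, length.out = 21)) / lx))
    got <- mean(cells, na.rm = TRUE)
    expect_lt(abs(got - pred), 0.05 * 4 + 0.1)
  }
  # single-leaflet and empty cells are undefined, never zero
  tm_fine <- thickness_map(traj, lipids, spacing = 0.2)
  expect_true(anyNA(tm_fine$thickness))
  expect_true(all(tm_fine$thickness[!is.na(tm_fine$thickness)] != 0))
})

test_that("lipid environment classes are exhaustive, exclusive and correct", {
  g <- small_system(rates = list(POPC = c(bulk = 0)), n_frames = 10,
                    n_per_leaflet = c(POPC = 50), seed = 12)
  lab <- classify_lipid_environment(g$traj, g$lipids, g$sites)
  expect_equal(dim(lab), c(100, 10))
  expect_true(all(lab %in% c("near-Sec61", "near-TRAP", "bulk", "intermediate")))

  # scripted distances: 1.5 nm from TRAP / far from everything
  coords <- array(0, c(4, 3, 1))
  coords[1, , 1] <- c(5.0, 5.0, 6.0)    # head A: 1.5 nm from TRAP bead
  coords[2, , 1] <- c(5, 5, 2)          # tail A
  coords[3, , 1] <- c(6.5, 5.0, 6.0)    # TRAP bead
  coords[4, , 1] <- c(20, 20, 6)        # Sec61 bead, far away
  traj <- trajectory(0, coords, c(30, 30, 12),
                     data.frame(name = c("PO4", "C4B", "BB1", "BB1"),
                                resname = c("POPC", "POPC", "SITE", "SITE"),
                                resid = 1:4))
  lipids <- lipid_set(1L, "POPC", 1L, 2L)
  sites <- protein_sites(list(TRAP = 3L, Sec61 = 4L))
  expect_equal(as.vector(classify_lipid_environment(traj, lipids, sites)),
               "near-TRAP")
  # 10 nm from everything -> bulk
  traj$coords[1, , 1] <- c(15, 15, 6)
  expect_equal(as.vector(classify_lipid_environment(traj, lipids, sites)),
               "bulk")
  # between the cutoffs -> intermediate
  traj$coords[1, , 1] <- c(6.5 + 2.5, 5, 6)
  expect_equal(as.vector(classify_lipid_environment(traj, lipids, sites)),
               "intermediate")
  expect_error(classify_lipid_environment(traj, lipids, sites,
                                          near_cutoff = 3, bulk_exclusion = 2))
})

test_that("per-class thickness on a thinned-annulus geometry recovers imposed values", {
  set.seed(14)
  n_lip <- 3000
  lx <- 20
  x <- runif(n_lip, 0, lx); y <- runif(n_lip, 0, lx)
  r <- sqrt((x - 10)^2 + (y - 10)^2)
  thin <- r < 2  # membrane thinned to 3 nm within 2 nm of the site
  half <- ifelse(thin, 1.5, 2.0)
  upper <- runif(n_lip) < 0.5
  coords <- array(NA_real_, c(2 * n_lip + 1, 3, 1))
  hidx <- seq_len(n_lip) * 2 - 1
  coords[hidx, 1, 1] <- x; coords[hidx, 2, 1] <- y
  coords[hidx, 3, 1] <- 6 + ifelse(upper, half, -half)
  coords[hidx + 1, , 1] <- coords[hidx, , 1]
  coords[hidx + 1, 3, 1] <- 6 + ifelse(upper, half - 3, -half + 3)
  coords[2 * n_lip + 1, , 1] <- c(10, 10, 6)  # site bead at the thin spot
  traj <- trajectory(0, coords, c(lx, lx, 12),
                     data.frame(name = c(rep(c("PO4", "C4B"), n_lip), "BB1"),
                                resname = c(rep("POPC", 2 * n_lip), "SITE"),
                                resid = c(rep(seq_len(n_lip), each = 2), 9999)))
  lipids <- lipid_set(seq_len(n_lip), "POPC", hidx, hidx + 1)
  sites <- protein_sites(list(X = 2L * n_lip + 1L))
  lab <- as.vector(classify_lipid_environment(traj, lipids, sites))
  st <- assign_leaflets(traj, lipids)
  up <- st$assigned[, 1] > 0
  zh <- traj$coords[lipids$head, 3, 1]
  near_th <- mean(zh[lab == "near-X" & up]) - mean(zh[lab == "near-X" & !up])
  bulk_th <- mean(zh[lab == "bulk" & up]) - mean(zh[lab == "bulk" & !up])
  expect_lt(abs(near_th - 3.0), 0.1)
  expect_lt(abs(bulk_th - 4.0), 0.1)
})

test_that("volumetric density conserves observations and localizes flips", {
  g <- small_system(rates = list(POPC = c(Sec61 = 3)), n_frames = 400, seed = 15)
  dm <- volumetric_density(g$traj, g$lipids$head, voxel = 1.0)
  # exact bookkeeping: sum(density) x voxel volume x frames = observations
  expect_equal(sum(dm$density) * prod(dm$voxel) * dm$n_frames, dm$n_obs)
  # headgroup density at midplane is elevated in the site column vs elsewhere
  iz_mid <- which.min(abs(dm$z - 6))
  ix_site <- which.min(abs(dm$x - 4.5)); iy_site <- which.min(abs(dm$y - 7.5))
  site_col <- dm$density[ix_site, iy_site, iz_mid]
  far <- dm$density[which.min(abs(dm$x - 12)), which.min(abs(dm$y - 2)), iz_mid]
  expect_gt(site_col, far)
  expect_error(volumetric_density(g$traj, g$lipids$head, voxel = 0.005),
               "degenerate")
})

test_that("uniform occupancy gives near-uniform voxel densities", {
  set.seed(16)
  n <- 5e4
  coords <- array(runif(n * 3 * 1, 0, 10), c(n, 3, 1))
  traj <- trajectory(0, coords, c(10, 10, 10),
                     data.frame(name = "PO4", resname = "POPC", resid = 1:n))
  dm <- volumetric_density(traj, seq_len(n), voxel = 2.5)
  p <- 1 / length(dm$density)
  counts <- dm$density * prod(dm$voxel)
  expect_true(all(abs(counts - n * p) < 3 * sqrt(n * p * (1 - p))))
})

test_that("volumetric density is invariant to joint translation with the reference", {
  g <- small_system(rates = list(POPC = c(bulk = 0)), n_frames = 20,
                    n_per_leaflet = c(POPC = 30), seed = 17)
  ref <- g$sites$reference
  d1 <- volumetric_density(g$traj, g$lipids$head, ref_indices = ref, voxel = 1)
  g$traj$coords[, 3, ] <- g$traj$coords[, 3, ] + 2.5
  d2 <- volumetric_density(g$traj, g$lipids$head, ref_indices = ref, voxel = 1)
  expect_equal(d1$density, d2$density)
})

test_that("pathway continuity agrees with a brute-force flood fill and is monotone", {
  mk_map <- function(dens) {
    structure(list(x = seq_len(dim(dens)[1]) - 0.5,
                   y = seq_len(dim(dens)[2]) - 0.5,
                   z = seq_len(dim(dens)[3]) - 0.5,
                   density = dens, voxel = c(1, 1, 1),
                   n_frames = 1, n_replicas = 1, n_obs = sum(dens)),
              class = "density_map3d")
  }
  # solid column spanning the leaflet planes -> continuous
  dens <- array(0, c(5, 5, 9))
  dens[3, 3, ] <- 1
  expect_true(pathway_continuity(mk_map(dens), c(1.5, 7.5), 0.5)$continuous)
  # a 3-voxel gap at the midplane breaks it
  dens[3, 3, 4:6] <- 0
  expect_false(pathway_continuity(mk_map(dens), c(1.5, 7.5), 0.5)$continuous)
  expect_error(pathway_continuity(mk_map(dens), c(1.5, 7.5), 0), "> 0")

  # random fields: implementation vs independent flood fill, plus monotonicity
  set.seed(18)
  for (i in 1:8) {
    dens <- array(runif(6 * 6 * 7), c(6, 6, 7))
    mp <- mk_map(dens)
    verdicts <- logical(0)
    for (th in c(0.3, 0.5, 0.7)) {
      got <- pathway_continuity(mp, c(0.5, 6.5), th)$continuous
      want <- flood_fill_bridges(dens >= th, 1, 7)
      expect_equal(got, want)
      verdicts <- c(verdicts, got)
    }
    # once broken at a threshold, broken for all larger thresholds
    expect_true(all(diff(as.integer(verdicts)) <= 0))
  }
})
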