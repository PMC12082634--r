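# Free-energy profiles from headgroup densities.
#
# Spontaneous flip-flops populate the whole transverse coordinate, so
# the equilibrium headgroup density rho(z), measured in a protein-fixed
# frame, yields the free-energy profile by Boltzmann inversion,
# dG(z) = -RT ln(rho(z)/rho0), with rho0 fixing dG = 0 at the
# equilibrium position.

#' Transverse number-density profile in a reference-group frame
#'
#' Per frame, z is measured relative to the centroid z of the reference
#' group (the membrane fluctuates, so a protein-fixed frame keeps the
#' profile sharp); counts are histogrammed into `n_slices` spanning the
#' box height and converted to number density per nm^3.
#'
#' @param traj a [trajectory()].
#' @param indices particle indices of the beads to histogram (e.g. all
#'   PO4 heads).
#' @param ref_indices reference-group particle indices; `NULL` uses the
#'   box centre as the frame.
#' @param n_slices number of z slices (default 300).
#' @return a [profile1d()] of density (1/nm^3) on z relative to the
#'   reference frame.
#' @export
density_profile <- function(traj, indices, ref_indices = NULL, n_slices = 300) {
  if (length(indices) == 0) stop("empty bead selection")
  if (n_slices < 10) stop("n_slices must be >= 10")
  lz <- mean(traj$box[, 3])
  edges <- seq(-lz / 2, lz / 2, length.out = n_slices + 1)
  counts <- numeric(n_slices)
  nf <- n_frames(traj)
  for (f in seq_len(nf)) {
    zref <- if (is.null(ref_indices)) lz / 2
            else mean(traj$coords[ref_indices, 3, f])
    zrel <- traj$coords[indices, 3, f] - zref
    # wrap into the box-height window about the reference
    zrel <- ((zrel + lz / 2) %% lz) - lz / 2
    h <- findInterval(zrel, edges, rightmost.closed = TRUE)
    h <- h[h >= 1 & h <= n_slices]
    counts <- counts + tabulate(h, nbins = n_slices)
  }
  slice_vol <- mean(traj$box[, 1]) * mean(traj$box[, 2]) * (lz / n_slices)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  profile1d(centers, counts / (nf * slice_vol), unit = "1/nm^3")
}

#' Boltzmann inversion of a density profile
#'
#' `dG(z) = -RT ln(rho(z)/rho0)` with `rho0` the maximum density, so the
#' global minimum of dG is 0. Zero-density bins become `+Inf`; interior
#' (non-edge) unsampled bins flag the profile `unsampled_core`, in which
#' case any barrier read off it is a lower bound.
#'
#' @param density a [profile1d()] of non-negative densities.
#' @param temperature temperature (K).
#' @return object of class `"fep"`: `z`, `dG` (kJ/mol), `temperature`,
#'   `error` (NULL here; attached by replica averaging), and the
#'   `unsampled_core` flag.
#' @export
boltzmann_invert <- function(density, temperature) {
  rho <- density$values
  if (any(rho < 0)) stop("density must be non-negative")
  if (all(rho <= 0)) stop("all-zero density; nothing to invert")
  rho0 <- max(rho)
  dG <- ifelse(rho > 0, -rt(temperature) * log(rho / rho0), Inf)
  inner <- range(which(rho > 0))
  unsampled <- any(!is.finite(dG[inner[1]:inner[2]]))
  structure(list(z = density$z, dG = dG, temperature = temperature,
                 error = NULL, unsampled_core = unsampled),
            class = "fep")
}

#' Construct a free-energy profile directly
#'
#' For profiles obtained outside the density route (e.g. AWH PMFs read
#' with [read_tabular_profile()], or analytic constructions). Values are
#' shifted so the minimum is 0, matching the Boltzmann-inversion
#' convention.
#'
#' @param z grid (nm).
#' @param dG free energy (kJ/mol).
#' @param temperature temperature (K).
#' @param error optional per-bin error (kJ/mol).
#' @return an `fep` object.
#' @export
free_energy_profile <- function(z, dG, temperature, error = NULL) {
  stopifnot(length(z) == length(dG))
  fin <- is.finite(dG)
  if (!any(fin)) stop("profile must be finite somewhere")
  dG <- dG - min(dG[fin])
  structure(list(z = as.numeric(z), dG = as.numeric(dG),
                 temperature = temperature, error = error,
                 unsampled_core = FALSE),
            class = "fep")
}

#' @export
print.fep <- function(x, ...) {
  fin <- is.finite(x$dG)
  cat(sprintf("<fep> %d bins at %g K, barrier-region max %.2f kJ/mol%s\n",
              length(x$z), x$temperature, max(x$dG[fin]),
              if (isTRUE(x$unsampled_core)) " [unsampled-core]" else ""))
  invisible(x)
}

# indices of local minima of a numeric vector (plateau-safe, endpoints
# count when strictly below their neighbour)
.local_minima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer())
  out <- integer()
  if (is.finite(v[1]) && v[1] < v[2]) out <- c(out, 1L)
  for (i in 2:(n - 1)) {
    if (is.finite(v[i]) && v[i] <= v[i - 1] && v[i] <= v[i + 1] &&
        (v[i] < v[i - 1] || v[i] < v[i + 1])) {
      out <- c(out, i)
    }
  }
  if (is.finite(v[n]) && v[n] < v[n - 1]) out <- c(out, n)
  out
}

#' Barrier height of a free-energy profile
#'
#' The barrier is the maximum dG between the two outermost minima of the
#' profile (the two leaflet equilibrium positions). Errors: mode
#' `"mirror"` uses the difference between the profile and its
#' leaflet-mirrored (z -> -z, re-zeroed) counterpart at the barrier;
#' mode `"replicas"` the SD of per-replica barrier heights.
#'
#' @param profile an `fep` (or [profile1d()] holding dG values).
#' @param replicas optional list of replica `fep`s for mode "replicas".
#' @param error one of `"mirror"`, `"replicas"`, `"none"`.
#' @return list with `barrier` (kJ/mol), `error`, `z_barrier` (nm) and
#'   `lower_bound` (TRUE when the profile has an unsampled core).
#' @export
barrier_height <- function(profile, replicas = NULL,
                           error = c("mirror", "none", "replicas")) {
  error <- match.arg(error)
  z <- profile$z
  dG <- if (!is.null(profile$dG)) profile$dG else profile$values
  mins <- .local_minima(dG)
  # include the global minimum even if it sits on an edge plateau
  mins <- sort(unique(c(mins, which.min(dG))))
  if (length(mins) < 2) {
    stop("shape error: profile lacks two minima flanking a central barrier")
  }
  lo <- min(mins); hi <- max(mins)
  seg <- dG[lo:hi]
  ib <- which.max(ifelse(is.finite(seg), seg, -Inf)) + lo - 1L
  g <- dG[ib]
  err <- NA_real_
  if (error == "mirror") {
    rev_dG <- rev(dG)
    rev_dG <- rev_dG - min(rev_dG[is.finite(rev_dG)])
    err <- abs(g - rev_dG[ib])
  } else if (error == "replicas") {
    if (is.null(replicas) || length(replicas) < 2) {
      stop("mode 'replicas' needs >= 2 replica profiles")
    }
    gs <- vapply(replicas, function(p) {
      barrier_height(p, error = "none")$barrier
    }, 0)
    g <- mean(gs)
    err <- stats::sd(gs)
  }
  list(barrier = g, error = err, z_barrier = z[ib],
       lower_bound = isTRUE(profile$unsampled_core))
}

# linear resampling of an fep onto a target grid
.resample_fep <- function(p, z_target, tol = 1e-6) {
  if (length(p$z) == length(z_target) && max(abs(p$z - z_target)) <= tol) {
    return(p)
  }
  if (min(z_target) < min(p$z) - tol || max(z_target) > max(p$z) + tol) {
    stop("grids do not overlap enough to resample")
  }
  v <- stats::approx(p$z, p$dG, xout = z_target, rule = 2)$y
  structure(list(z = z_target, dG = v, temperature = p$temperature,
                 error = NULL, unsampled_core = isTRUE(p$unsampled_core)),
            class = "fep")
}

#' Entropy/enthalpy decomposition of free-energy profiles
#'
#' Finite-difference decomposition assuming the entropy component is
#' constant across each temperature pair: for a pair (T1, T2),
#' `dS(z) = -(dG(z,T2) - dG(z,T1)) / (T2 - T1)` and
#' `dH(z) = dG(z,T_mid) + T_mid dS(z)`. Reported values are the mean of
#' the pair estimates; the per-bin error is their absolute difference.
#' The identity `dG = dH + (-T dS)` holds pointwise at `T_mid` by
#' construction.
#'
#' @param profiles named list of `fep` objects; names (or their
#'   `$temperature` fields) give the temperatures in K. Must contain all
#'   pair temperatures and `T_mid`.
#' @param pairs list of temperature pairs (default `(300, 320)` and
#'   `(290, 330)`).
#' @param T_mid evaluation temperature (default 310 K).
#' @return object of class `"thermo_decomp"`: `z`, `dG`, `dH`, `mTdS`
#'   (= -T_mid dS), `error`, `T_mid`.
#' @export
decompose_thermo <- function(profiles,
                             pairs = list(c(300, 320), c(290, 330)),
                             T_mid = 310) {
  temps <- vapply(profiles, function(p) p$temperature, 0)
  need <- sort(unique(c(unlist(pairs), T_mid)))
  if (!all(need %in% temps)) {
    stop("profiles must cover temperatures ",
         paste(need, collapse = ", "), " K")
  }
  at <- function(tt) profiles[[which(temps == tt)[1]]]
  z <- at(T_mid)$z
  g_mid <- at(T_mid)$dG
  dS_pairs <- lapply(pairs, function(pr) {
    T1 <- min(pr); T2 <- max(pr)
    g1 <- .resample_fep(at(T1), z)$dG
    g2 <- .resample_fep(at(T2), z)$dG
    -(g2 - g1) / (T2 - T1)
  })
  dS <- Reduce(`+`, dS_pairs) / length(dS_pairs)
  err <- if (length(dS_pairs) >= 2) {
    abs(dS_pairs[[1]] - dS_pairs[[2]]) * T_mid
  } else {
    rep(NA_real_, length(z))
  }
  dH <- g_mid + T_mid * dS
  structure(list(z = z, dG = g_mid, dH = dH, mTdS = -T_mid * dS,
                 error = err, T_mid = T_mid),
            class = "thermo_decomp")
}

#' Membrane thinning vs flip-flop barrier
#'
#' Least-squares line through (local membrane thickness, flip-flop
#' barrier) pairs; `predict_barrier_reduction` evaluates the fitted line
#' at the bulk and locally thinned thickness and returns the difference,
#' i.e. the barrier reduction attributable to protein-induced thinning.
#'
#' @param thickness membrane thicknesses (nm), >= 2 distinct values.
#' @param barrier flip-flop barriers (kJ/mol).
#' @return object of class `"thickness_barrier_fit"`: `slope`
#'   (kJ/mol/nm), `intercept`, their SEs, and the input pairs.
#' @export
fit_thickness_barrier <- function(thickness, barrier) {
  stopifnot(length(thickness) == length(barrier), length(thickness) >= 2)
  if (length(unique(thickness)) < 2) {
    stop("singular fit: thicknesses must not be identical")
  }
  fit <- stats::lm(barrier ~ thickness)
  cf <- summary(fit)$coefficients
  structure(list(slope = unname(cf["thickness", "Estimate"]),
                 intercept = unname(cf["(Intercept)", "Estimate"]),
                 slope_se = unname(cf["thickness", "Std. Error"]),
                 intercept_se = if (nrow(cf) > 1 && length(thickness) > 2)
                   unname(cf["(Intercept)", "Std. Error"]) else NA_real_,
                 pairs = data.frame(thickness = thickness, barrier = barrier)),
            class = "thickness_barrier_fit")
}

#' @rdname fit_thickness_barrier
#' @param fit a `thickness_barrier_fit`.
#' @param thickness_local,thickness_bulk thickness next to the protein
#'   and in the unperturbed membrane (nm).
#' @return `predict_barrier_reduction`: the barrier reduction ddG
#'   (kJ/mol), positive when the local membrane is thinner.
#' @export
predict_barrier_reduction <- function(fit, thickness_local, thickness_bulk) {
  stopifnot(inherits(fit, "thickness_barrier_fit"))
  (fit$intercept + fit$slope * thickness_bulk) -
    (fit$intercept + fit$slope * thickness_local)
}
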