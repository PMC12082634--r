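# Synthetic membrane trajectories with known ground truth.
#
# The generator emulates the features the trajectory analyses rely on:
# head/tail bead pairs whose transverse positions fluctuate around the
# leaflet planes, lateral diffusion in a periodic box, flip-flop events
# drawn as a Poisson process and localized at named protein sites, and a
# linear transverse transit during each flip. It deliberately contains
# no force-field physics: sites are static bead columns and leaflets are
# ideal Gaussians.

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Specification for a synthetic membrane trajectory
#'
#' Defaults mimic the scale of a coarse-grained translocon membrane
#' patch: a 15 x 15 x 12 nm box, leaflet planes at +/- 2 nm about the
#' midplane, transverse headgroup fluctuation 0.3 nm, and 20 us of
#' frames at 10 ns spacing.
#'
#' @param n_per_leaflet named integer vector: lipids per leaflet per
#'   type, e.g. `c(POPC = 300)`.
#' @param rates named list: `rates[[type]][[site]]` is the true system
#'   flip-flop rate (events per us) localized at that site; the site
#'   name `"bulk"` means unlocalized events.
#' @param sites named list of lateral site centres `c(x, y)` in nm.
#' @param leaflet_offset leaflet plane distance from the midplane (nm).
#' @param chain_dz head-to-tail transverse bead separation (nm).
#' @param sigma_z transverse fluctuation SD of each bead (nm).
#' @param sigma_xy lateral random-walk step SD per frame (nm).
#' @param transit_ns duration of the linear transverse transit of a flip.
#' @param box box edge lengths (nm).
#' @param n_frames,dt_ns number and spacing (ns) of saved frames.
#' @param temperature temperature label (K).
#' @param seed RNG seed.
#' @return object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_per_leaflet = c(POPC = 300),
                           rates = list(POPC = c(bulk = 0)),
                           sites = list(),
                           leaflet_offset = 2.0, chain_dz = 3.0,
                           sigma_z = 0.3, sigma_xy = 0.1,
                           transit_ns = 50,
                           box = c(15, 15, 12),
                           n_frames = 2000, dt_ns = 10,
                           temperature = 310, seed = 1L) {
  stopifnot(length(n_per_leaflet) >= 1, !is.null(names(n_per_leaflet)))
  duration_ns <- n_frames * dt_ns
  if (transit_ns >= duration_ns) stop("transit time must be shorter than the trajectory")
  if (sigma_z >= leaflet_offset) stop("sigma_z must be below the leaflet offset")
  for (type in names(rates)) {
    if (any(rates[[type]] < 0)) stop("rates must be >= 0")
    for (s in names(rates[[type]])) {
      if (s != "bulk" && !(s %in% names(sites))) {
        stop("rate refers to unknown site '", s, "'")
      }
    }
  }
  structure(list(n_per_leaflet = n_per_leaflet, rates = rates, sites = sites,
                 leaflet_offset = leaflet_offset, chain_dz = chain_dz,
                 sigma_z = sigma_z, sigma_xy = sigma_xy,
                 transit_ns = transit_ns, box = box,
                 n_frames = as.integer(n_frames), dt_ns = dt_ns,
                 temperature = temperature, seed = seed),
            class = "synthetic_spec")
}

#' Generate a synthetic trajectory with ground-truth flip-flop events
#'
#' Lipids are head+tail bead pairs. Between events the head z is
#' Gaussian about its leaflet plane and the tail sits on the midplane
#' side, so the head-tail z separation carries the leaflet orientation.
#' Flip events are a Poisson process at the specified per-site rates; a
#' flipping lipid is first placed laterally within 1 nm of its site
#' centre, then its mean transverse position traverses the membrane
#' linearly over the transit time. If the lipid drawn for an event is
#' still in transit the event is queued until it is free (never
#' dropped). Identical seeds give identical output.
#'
#' @param spec a [synthetic_spec()].
#' @return list with elements `traj` ([trajectory()]), `lipids`
#'   ([lipid_set()]), `sites` ([protein_sites()]) and `events` (the
#'   ground-truth event log: `lipid_id`, `type`, `t_start_ns`,
#'   `direction`, `site`).
#' @export
generate_trajectory <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  .with_seed(spec$seed, .generate_trajectory_impl(spec))
}

.generate_trajectory_impl <- function(spec) {
  nf <- spec$n_frames
  dt <- spec$dt_ns
  times <- (seq_len(nf) - 1) * dt
  duration_ns <- nf * dt
  Lx <- spec$box[1]; Ly <- spec$box[2]; Lz <- spec$box[3]
  zmid <- Lz / 2

  types <- rep(names(spec$n_per_leaflet), times = 2 * spec$n_per_leaflet)
  n_lip <- length(types)
  # alternate leaflets within each type so both start balanced
  sign0 <- unlist(lapply(spec$n_per_leaflet, function(n) rep(c(1, -1), each = n)),
                  use.names = FALSE)

  ## ground-truth events -------------------------------------------------
  ev <- list(lipid = integer(), type = character(), t = numeric(),
             dir = character(), site = character())
  raw <- list()
  for (type in names(spec$rates)) {
    for (s in names(spec$rates[[type]])) {
      r <- spec$rates[[type]][[s]]
      if (r <= 0) next
      n_ev <- stats::rpois(1, r * duration_ns / 1000)
      if (n_ev == 0) next
      tt <- sort(stats::runif(n_ev, 0, duration_ns - spec$transit_ns - dt))
      raw[[length(raw) + 1L]] <- data.frame(type = type, t = tt, site = s)
    }
  }
  sign_now <- sign0
  busy_until <- rep(-Inf, n_lip)
  if (length(raw) > 0) {
    raw <- do.call(rbind, raw)
    raw <- raw[order(raw$t), , drop = FALSE]
    for (k in seq_len(nrow(raw))) {
      t0 <- raw$t[k]
      cand <- which(types == raw$type[k])
      free <- cand[busy_until[cand] <= t0]
      if (length(free) == 0) {
        # queue after the earliest transit in progress finishes
        t0 <- min(busy_until[cand]) + dt
        if (t0 > duration_ns - spec$transit_ns - dt) next
        free <- cand[busy_until[cand] <= t0]
        sk_log("event queued to t=", round(t0, 2), " ns (all ", raw$type[k],
               " lipids in transit)")
      }
      l <- if (length(free) == 1) free else sample(free, 1)
      ev$lipid <- c(ev$lipid, l)
      ev$type <- c(ev$type, raw$type[k])
      ev$t <- c(ev$t, t0)
      ev$dir <- c(ev$dir, if (sign_now[l] > 0) "up_to_down" else "down_to_up")
      ev$site <- c(ev$site, raw$site[k])
      sign_now[l] <- -sign_now[l]
      busy_until[l] <- t0 + spec$transit_ns + dt
    }
  }
  events <- data.frame(lipid_id = ev$lipid, type = ev$type, t_start_ns = ev$t,
                       direction = ev$dir, site = ev$site,
                       stringsAsFactors = FALSE)
  events <- events[order(events$t_start_ns), , drop = FALSE]
  rownames(events) <- NULL

  ## mean transverse positions over frames (rel. to midplane) ------------
  # heads sit on the leaflet plane, tails on the midplane side; during a
  # transit both interpolate linearly to their mirrored positions
  tail0 <- spec$leaflet_offset - spec$chain_dz   # e.g. -1 nm for upper lipids
  mean_zrel <- matrix(rep(sign0 * spec$leaflet_offset, nf), nrow = n_lip)
  tail_zrel <- matrix(rep(sign0 * tail0, nf), nrow = n_lip)
  for (k in seq_len(nrow(events))) {
    l <- events$lipid_id[k]
    t0 <- events$t_start_ns[k]
    s0 <- if (events$direction[k] == "up_to_down") 1 else -1
    in_transit <- times >= t0 & times <= t0 + spec$transit_ns
    after <- times > t0 + spec$transit_ns
    frac <- (times[in_transit] - t0) / spec$transit_ns
    mean_zrel[l, in_transit] <- s0 * spec$leaflet_offset * (1 - 2 * frac)
    mean_zrel[l, after] <- -s0 * spec$leaflet_offset
    tail_zrel[l, in_transit] <- s0 * tail0 * (1 - 2 * frac)
    tail_zrel[l, after] <- -s0 * tail0
  }

  ## lateral random walks ------------------------------------------------
  steps_x <- matrix(stats::rnorm(n_lip * nf, 0, spec$sigma_xy), n_lip, nf)
  steps_y <- matrix(stats::rnorm(n_lip * nf, 0, spec$sigma_xy), n_lip, nf)
  steps_x[, 1] <- stats::runif(n_lip, 0, Lx)
  steps_y[, 1] <- stats::runif(n_lip, 0, Ly)
  hx <- t(apply(steps_x, 1, cumsum))
  hy <- t(apply(steps_y, 1, cumsum))
  # teleport flipping lipids next to their site centre at event start
  for (k in seq_len(nrow(events))) {
    s <- events$site[k]
    if (s == "bulk" || !(s %in% names(spec$sites))) next
    l <- events$lipid_id[k]
    f0 <- findInterval(events$t_start_ns[k], times)
    ang <- stats::runif(1, 0, 2 * pi)
    rad <- sqrt(stats::runif(1)) * 1.0       # uniform in a 1 nm disk
    target <- spec$sites[[s]] + rad * c(cos(ang), sin(ang))
    hx[l, f0:nf] <- hx[l, f0:nf] + (target[1] - hx[l, f0])
    hy[l, f0:nf] <- hy[l, f0:nf] + (target[2] - hy[l, f0])
  }
  hx <- hx %% Lx
  hy <- hy %% Ly

  ## assemble coordinates ------------------------------------------------
  hz <- zmid + mean_zrel + matrix(stats::rnorm(n_lip * nf, 0, spec$sigma_z),
                                  n_lip, nf)
  tz <- zmid + tail_zrel +
    matrix(stats::rnorm(n_lip * nf, 0, spec$sigma_z), n_lip, nf)
  tx <- (hx + matrix(stats::rnorm(n_lip * nf, 0, 0.1), n_lip, nf)) %% Lx
  ty <- (hy + matrix(stats::rnorm(n_lip * nf, 0, 0.1), n_lip, nf)) %% Ly

  site_beads <- .site_bead_columns(spec, zmid)
  n_site <- nrow(site_beads$meta)
  n_atoms <- 2L * n_lip + n_site
  coords <- array(NA_real_, dim = c(n_atoms, 3L, nf))
  head_idx <- 2L * seq_len(n_lip) - 1L
  tail_idx <- 2L * seq_len(n_lip)
  coords[head_idx, 1, ] <- hx; coords[head_idx, 2, ] <- hy
  coords[head_idx, 3, ] <- hz
  coords[tail_idx, 1, ] <- tx; coords[tail_idx, 2, ] <- ty
  coords[tail_idx, 3, ] <- tz
  if (n_site > 0) {
    for (d in 1:3) coords[2L * n_lip + seq_len(n_site), d, ] <- site_beads$xyz[, d]
  }

  head_names <- vapply(types, function(tp) "PO4", "")
  tail_names <- vapply(types, function(tp) "C4B", "")
  atoms <- data.frame(
    name = character(n_atoms), resname = character(n_atoms),
    resid = integer(n_atoms), chain = NA_character_)
  atoms$name[head_idx] <- head_names
  atoms$name[tail_idx] <- tail_names
  atoms$resname[head_idx] <- types
  atoms$resname[tail_idx] <- types
  atoms$resid[head_idx] <- seq_len(n_lip)
  atoms$resid[tail_idx] <- seq_len(n_lip)
  if (n_site > 0) {
    atoms$name[2L * n_lip + seq_len(n_site)] <- site_beads$meta$name
    atoms$resname[2L * n_lip + seq_len(n_site)] <- site_beads$meta$resname
    atoms$resid[2L * n_lip + seq_len(n_site)] <- site_beads$meta$resid
  }

  traj <- trajectory(times = times, coords = coords, box = spec$box,
                     atoms = atoms)
  lipids <- lipid_set(seq_len(n_lip), types, head_idx, tail_idx,
                      n_atoms = n_atoms)
  site_list <- list()
  for (nm in names(spec$sites)) {
    site_list[[nm]] <- 2L * n_lip + which(site_beads$meta$site == nm)
  }
  sites <- protein_sites(site_list,
                         reference = if (n_site > 0) 2L * n_lip + seq_len(n_site)
                                     else integer())
  list(traj = traj, lipids = lipids, sites = sites, events = events)
}

# static vertical bead columns marking each protein site; spans the
# leaflet planes so pathway distances are small for site-localized flips
.site_bead_columns <- function(spec, zmid) {
  if (length(spec$sites) == 0) {
    return(list(meta = data.frame(name = character(), resname = character(),
                                  resid = integer(), site = character()),
                xyz = matrix(numeric(), ncol = 3)))
  }
  zs <- seq(-spec$leaflet_offset, spec$leaflet_offset, by = 0.5)
  meta <- list(); xyz <- list(); rid <- 10000L
  for (nm in names(spec$sites)) {
    rid <- rid + 1L
    meta[[nm]] <- data.frame(name = sprintf("BB%d", seq_along(zs)),
                             resname = "SITE", resid = rid, site = nm)
    xyz[[nm]] <- cbind(spec$sites[[nm]][1], spec$sites[[nm]][2], zmid + zs)
  }
  list(meta = do.call(rbind, meta), xyz = do.call(rbind, xyz))
}

#' Generate a temperature series with Arrhenius-true rates
#'
#' True rates follow `k(T) = exp(lnA - E_A / (R T))` with `k` in events
#' per microsecond. Returns one synthetic spec per temperature and
#' replica (total site rates rescaled so their sum is `k(T)`), plus the
#' exact true rates for closed-form checks.
#'
#' @param E_A activation energy (kJ/mol).
#' @param lnA log prefactor (ln of 1/us).
#' @param temperatures vector of at least two distinct temperatures (K).
#' @param template a [synthetic_spec()] whose site-rate pattern sets the
#'   relative split across sites and lipid types.
#' @param n_replicas replicas per temperature.
#' @return list with `true_rates` (data frame `temperature`, `k_true`)
#'   and `specs` (list of specs, one per temperature x replica, with
#'   fields `$temperature` and `$seed` set).
#' @export
generate_arrhenius_series <- function(E_A, lnA, temperatures,
                                      template = synthetic_spec(),
                                      n_replicas = 1L) {
  temperatures <- as.numeric(temperatures)
  if (length(unique(temperatures)) < 2) {
    stop("need at least two distinct temperatures (a single one leaves the fit underdetermined)")
  }
  if (any(temperatures <= 0)) stop("temperatures must be > 0")
  k_true <- exp(lnA - E_A / (RGAS * temperatures))
  tot <- sum(unlist(template$rates))
  if (tot <= 0) stop("template must have a positive total rate to set the site split")
  specs <- list()
  i <- 0L
  for (j in seq_along(temperatures)) {
    for (rep_i in seq_len(n_replicas)) {
      i <- i + 1L
      sp <- template
      sp$rates <- lapply(template$rates, function(v) v * k_true[j] / tot)
      sp$temperature <- temperatures[j]
      sp$seed <- template$seed + 1000L * j + rep_i
      sp$replica <- rep_i
      specs[[i]] <- sp
    }
  }
  list(true_rates = data.frame(temperature = temperatures, k_true = k_true),
       specs = specs)
}

#' Draw transverse positions from a free-energy profile
#'
#' Samples z proportional to `exp(-dG(z)/RT)` by inverse-CDF on the
#' profile grid (uniform within bins), the inverse operation of
#' [boltzmann_invert()].
#'
#' @param profile a [profile1d()] or `fep` object holding dG (kJ/mol).
#' @param temperature temperature (K).
#' @param n number of samples.
#' @param seed RNG seed (`NULL` to use the current RNG state).
#' @return numeric vector of z samples (nm).
#' @export
sample_from_pmf <- function(profile, temperature, n, seed = NULL) {
  z <- profile$z
  dG <- if (!is.null(profile$dG)) profile$dG else profile$values
  w <- exp(-dG / rt(temperature))
  w[!is.finite(w)] <- 0
  if (sum(w) <= 0) stop("profile is infinite everywhere; nothing to sample")
  dz <- if (length(z) > 1) z[2] - z[1] else 1
  .with_seed(seed, {
    bin <- sample.int(length(z), n, replace = TRUE, prob = w)
    z[bin] + stats::runif(n, -dz / 2, dz / 2)
  })
}

#' Generate a noisy synthetic assay curve
#'
#' Forward-model fluorescence from [simulate_assay()] plus i.i.d.
#' Gaussian noise.
#'
#' @param model an [assay_model()].
#' @param times observation times (s).
#' @param sigma noise SD (fluorescence units); `0` returns the exact
#'   forward model.
#' @param seed RNG seed.
#' @return an `assay_curve` (see [simulate_assay()]).
#' @export
generate_assay_curve <- function(model, times, sigma = 0, seed = NULL) {
  stopifnot(sigma >= 0)
  curve <- simulate_assay(model, times)
  if (sigma > 0) {
    curve$F <- curve$F + .with_seed(seed, stats::rnorm(length(times), 0, sigma))
  }
  curve
}
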