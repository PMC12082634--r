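# Leaflet assignment, flip-flop detection, pathway attribution and rate
# statistics.
#
# A lipid's orientation is read from the transverse separation of its
# head and tail beads, dz = z_head - z_tail. With the default (physical)
# sign convention, dz >= +d marks the upper leaflet, dz <= -d the lower,
# anything in between is undetermined. The assigned leaflet is carried
# with hysteresis: it changes only when the instantaneous state reaches
# the opposite leaflet, so midplane dwellers are never double-counted.

#' Assign lipids to leaflets with a hysteresis criterion
#'
#' @param traj a [trajectory()].
#' @param lipids a [lipid_set()].
#' @param threshold head-tail z separation threshold d (nm); the default
#'   2.1 nm is the value at which detected event counts plateau for
#'   coarse-grained phospholipids.
#' @param leaflet_sign `+1` (default): head above tail means upper
#'   leaflet; `-1` inverts the convention. Event counts are invariant to
#'   this switch.
#' @return object of class `"leaflet_series"`: matrices `inst` and
#'   `assigned` (`n_lipids x n_frames`, values +1 upper / -1 lower, 0 =
#'   undetermined in `inst`), plus `lipid_id` and `times`.
#' @export
assign_leaflets <- function(traj, lipids, threshold = 2.1, leaflet_sign = 1) {
  stopifnot(threshold > 0, leaflet_sign %in% c(-1, 1))
  if (threshold >= min(traj$box[, 3]) / 2) {
    warning("threshold >= half the box height; no lipid can reach it")
  }
  dz <- (traj$coords[lipids$head, 3, , drop = FALSE] -
         traj$coords[lipids$tail, 3, , drop = FALSE])[, 1, ] * leaflet_sign
  dz <- matrix(dz, nrow = nrow(lipids))
  inst <- matrix(0L, nrow(dz), ncol(dz))
  inst[dz >= threshold] <- 1L
  inst[dz <= -threshold] <- -1L

  # initial assignment: side of the membrane midplane at frame 0
  zh0 <- traj$coords[lipids$head, 3, 1]
  mid <- mean(zh0)
  state <- ifelse(zh0 >= mid, 1L, -1L)
  assigned <- matrix(0L, nrow(dz), ncol(dz))
  for (f in seq_len(ncol(dz))) {
    cross <- inst[, f] == -state
    state[cross] <- -state[cross]
    assigned[, f] <- state
  }
  structure(list(inst = inst, assigned = assigned,
                 lipid_id = lipids$lipid_id, times = traj$times),
            class = "leaflet_series")
}

#' Detect flip-flop events from a leaflet assignment
#'
#' One event per assigned-leaflet change, timestamped at the first frame
#' of the new assignment; the head bead position at that frame is kept
#' for pathway attribution. Directions of one lipid's events alternate
#' by construction of the hysteresis assignment.
#'
#' @param states a `leaflet_series` from [assign_leaflets()].
#' @param traj the trajectory the states were computed on.
#' @param lipids the [lipid_set()] used.
#' @return data frame of class `c("flipflop_events", "data.frame")` with
#'   columns `lipid_id`, `type`, `time_ns`, `direction`, `x`, `y`, `z`,
#'   `site` (initialized `"bulk"`).
#' @export
detect_events <- function(states, traj, lipids) {
  stopifnot(inherits(states, "leaflet_series"))
  chg <- states$assigned[, -1, drop = FALSE] !=
    states$assigned[, -ncol(states$assigned), drop = FALSE]
  idx <- which(chg, arr.ind = TRUE)
  if (length(idx) == 0) {
    ev <- data.frame(lipid_id = integer(), type = character(),
                     time_ns = numeric(), direction = character(),
                     x = numeric(), y = numeric(), z = numeric(),
                     site = character())
    return(structure(ev, class = c("flipflop_events", "data.frame")))
  }
  li <- idx[, 1]
  fi <- idx[, 2] + 1L      # first frame of the new assignment
  new_state <- states$assigned[cbind(li, fi)]
  hpos <- t(vapply(seq_along(li), function(k) {
    traj$coords[lipids$head[li[k]], , fi[k]]
  }, numeric(3)))
  ev <- data.frame(
    lipid_id = lipids$lipid_id[li],
    type = lipids$type[li],
    time_ns = states$times[fi],
    direction = ifelse(new_state > 0, "down_to_up", "up_to_down"),
    x = hpos[, 1], y = hpos[, 2], z = hpos[, 3],
    site = "bulk", stringsAsFactors = FALSE)
  ev <- ev[order(ev$time_ns, ev$lipid_id), , drop = FALSE]
  rownames(ev) <- NULL
  structure(ev, class = c("flipflop_events", "data.frame"))
}

#' Attribute flip-flop events to protein scrambling pathways
#'
#' An event is assigned to the site whose pathway beads have the
#' smallest 3D distance to the head position at the event frame,
#' provided that distance is at most `cutoff`; otherwise it stays
#' `"bulk"`. Ties break by distance, then site-name order.
#'
#' @param events a `flipflop_events` data frame.
#' @param sites a [protein_sites()].
#' @param traj the trajectory (site beads are read at the event frame).
#' @param cutoff attribution distance (nm); events count as initiated at
#'   a pathway when within this distance of it.
#' @return `events` with the `site` column filled.
#' @export
assign_events_to_sites <- function(events, sites, traj, cutoff = 2.0) {
  stopifnot(inherits(sites, "protein_sites"))
  if (length(sites$sites) == 0 || nrow(events) == 0) return(events)
  site_names <- sort(names(sites$sites))
  frame_of <- match(events$time_ns, traj$times)
  for (k in seq_len(nrow(events))) {
    f <- frame_of[k]
    p <- c(events$x[k], events$y[k], events$z[k])
    best <- Inf; best_site <- "bulk"
    for (nm in site_names) {
      b <- traj$coords[sites$sites[[nm]], , f, drop = FALSE][, , 1]
      b <- matrix(b, ncol = 3)
      d <- sqrt(min((b[, 1] - p[1])^2 + (b[, 2] - p[2])^2 + (b[, 3] - p[3])^2))
      if (d <= cutoff && d < best) { best <- d; best_site <- nm }
    }
    events$site[k] <- best_site
  }
  events
}

#' Scrambling rates with replica standard errors
#'
#' For each (site, lipid type): the rate is the mean over replicas of
#' events per microsecond, the SE the sample SD over replicas divided by
#' sqrt(n). A `"total"` row per site sums the per-type rates, with its
#' SE from the per-replica totals.
#'
#' @param events_by_replica list of `flipflop_events` data frames, one
#'   per replica (site column filled or all `"bulk"`).
#' @param durations_us replica durations in microseconds (recycled).
#' @param sites,types labels to tabulate (default: those observed).
#' @return a [rate_table()].
#' @export
compute_rates <- function(events_by_replica, durations_us,
                          sites = NULL, types = NULL) {
  n_rep <- length(events_by_replica)
  stopifnot(n_rep >= 1)
  durations_us <- rep_len(durations_us, n_rep)
  if (any(durations_us <= 0)) stop("zero-duration replica")
  all_ev <- do.call(rbind, lapply(events_by_replica, as.data.frame))
  if (is.null(sites)) {
    sites <- unique(c(all_ev$site, "bulk"))
  }
  if (is.null(types)) {
    types <- unique(all_ev$type)
    if (length(types) == 0) types <- "all"
  }
  rows <- list()
  for (s in sites) {
    per_rep_tot <- numeric(n_rep)
    tot_events <- 0L
    for (tp in types) {
      k_rep <- vapply(seq_len(n_rep), function(r) {
        e <- events_by_replica[[r]]
        sum(e$site == s & e$type == tp) / durations_us[r]
      }, 0)
      per_rep_tot <- per_rep_tot + k_rep
      n_ev <- sum(vapply(seq_len(n_rep), function(r) {
        e <- events_by_replica[[r]]
        sum(e$site == s & e$type == tp)
      }, 0L))
      tot_events <- tot_events + n_ev
      rows[[length(rows) + 1L]] <- data.frame(
        site = s, lipid_type = tp, rate = mean(k_rep),
        se = if (n_rep > 1) stats::sd(k_rep) / sqrt(n_rep) else 0,
        n_replicas = n_rep, total_events = n_ev)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      site = s, lipid_type = "total", rate = mean(per_rep_tot),
      se = if (n_rep > 1) stats::sd(per_rep_tot) / sqrt(n_rep) else 0,
      n_replicas = n_rep, total_events = tot_events)
  }
  d <- do.call(rbind, rows)
  rate_table(d$site, d$lipid_type, d$rate, d$se, d$n_replicas, d$total_events)
}

#' Detection-threshold sensitivity scan
#'
#' Runs the full assign-detect-rate pipeline at each threshold and
#' reports counts and rates, plus the widest contiguous plateau window
#' within which the rate varies by less than `plateau_tol` (relative
#' range).
#'
#' @param traj,lipids as in [assign_leaflets()].
#' @param thresholds ascending thresholds (nm).
#' @param duration_us trajectory duration for the rate (defaults to the
#'   time span).
#' @param plateau_tol relative rate variation defining the plateau.
#' @return list with `scan` (data frame `threshold`, `n_events`, `rate`)
#'   and `plateau` (`c(lo, hi)` thresholds, or `NULL`).
#' @export
threshold_scan <- function(traj, lipids, thresholds,
                           duration_us = NULL, plateau_tol = 0.10) {
  stopifnot(!is.unsorted(thresholds))
  if (is.null(duration_us)) {
    duration_us <- (max(traj$times) - min(traj$times)) / 1000
  }
  n_ev <- vapply(thresholds, function(d) {
    st <- suppressWarnings(assign_leaflets(traj, lipids, threshold = d))
    nrow(detect_events(st, traj, lipids))
  }, 0L)
  scan <- data.frame(threshold = thresholds, n_events = n_ev,
                     rate = n_ev / duration_us)
  best <- NULL
  for (i in seq_along(thresholds)) {
    for (j in seq(i, length(thresholds))) {
      w <- scan$rate[i:j]
      ok <- if (max(w) == 0) TRUE else (max(w) - min(w)) / max(w) < plateau_tol
      if (ok && (is.null(best) ||
                 thresholds[j] - thresholds[i] > best[2] - best[1])) {
        best <- c(thresholds[i], thresholds[j])
      }
    }
  }
  list(scan = scan, plateau = best)
}

#' Arrhenius analysis of temperature-dependent rates
#'
#' Ordinary least squares of `ln k` on `1/T`; the activation energy is
#' `-slope * R`. With `weighted = TRUE`, points are weighted by the
#' inverse squared relative error (`(k/se)^2`), the appropriate weight
#' for `ln k` when `se` is the SE of `k`.
#'
#' @param temperature temperatures (K), at least 3 distinct.
#' @param k rates (1/us), all > 0.
#' @param se optional rate SEs (needed for `weighted`).
#' @param weighted logical.
#' @return object of class `"arrhenius_fit"`: `E_A`, `lnA`, `E_A_se`,
#'   `lnA_se` and `residuals`.
#' @export
fit_arrhenius <- function(temperature, k, se = NULL, weighted = FALSE) {
  if (length(unique(temperature)) < 3) stop("need >= 3 distinct temperatures")
  if (any(k <= 0)) {
    stop("all rates must be > 0 for the log fit; exclude zero-rate points")
  }
  w <- NULL
  if (weighted) {
    if (is.null(se) || any(se <= 0)) stop("weighted fit needs positive SEs")
    w <- (k / se)^2
  }
  d <- data.frame(x = 1 / temperature, y = log(k))
  fit <- stats::lm(y ~ x, data = d, weights = w)
  # noiseless (exact-Arrhenius) input is legitimate here; keep lm quiet
  cf <- suppressWarnings(summary(fit))$coefficients
  structure(list(E_A = -unname(cf["x", "Estimate"]) * RGAS,
                 lnA = unname(cf["(Intercept)", "Estimate"]),
                 E_A_se = unname(cf["x", "Std. Error"]) * RGAS,
                 lnA_se = unname(cf["(Intercept)", "Std. Error"]),
                 residuals = unname(stats::residuals(fit)),
                 lm = fit),
            class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf("<arrhenius_fit> E_A = %.2f +/- %.2f kJ/mol, lnA = %.2f +/- %.2f\n",
              x$E_A, x$E_A_se, x$lnA, x$lnA_se))
  invisible(x)
}

#' Transition-state (Eyring) rate and barrier-change speed-up
#'
#' `eyring_rate` gives `kappa * (k_B T / h) * exp(-G / RT)` in 1/s.
#' `eyring_speedup` is the fold acceleration from lowering the barrier
#' from `dg_ref` to `dg_new`, equal to the ratio of the Eyring rates.
#' `scaled_half_life` rescales a reference half-life by that fold.
#'
#' @param g,dg_ref,dg_new free-energy barriers (kJ/mol).
#' @param temperature temperature (K).
#' @param kappa transmission coefficient (unity by convention).
#' @param t_ref reference half-life (s).
#' @param fold speed-up factor.
#' @return numeric scalar.
#' @export
eyring_rate <- function(g, temperature, kappa = 1) {
  stopifnot(temperature > 0)
  kappa * (KBOLTZ * temperature / PLANCK) * exp(-g / rt(temperature))
}

#' @rdname eyring_rate
#' @export
eyring_speedup <- function(dg_ref, dg_new, temperature) {
  stopifnot(temperature > 0)
  exp((dg_ref - dg_new) / rt(temperature))
}

#' @rdname eyring_rate
#' @export
scaled_half_life <- function(t_ref, fold) t_ref / fold

#' Compare per-replica scrambling rates between two systems
#'
#' Welch two-sample t-test on per-replica rates (two-sided). Identical
#' groups return p = 1.
#'
#' @param rates_a,rates_b numeric vectors of per-replica rates, length
#'   >= 2 each.
#' @return list with `p_value`, `statistic`, `estimate` (group means).
#' @export
compare_rates <- function(rates_a, rates_b) {
  if (length(rates_a) < 2 || length(rates_b) < 2) {
    stop("need at least 2 replicas per group")
  }
  if (stats::sd(rates_a) == 0 && stats::sd(rates_b) == 0) {
    p <- if (mean(rates_a) == mean(rates_b)) 1 else 0
    return(list(p_value = p, statistic = NA_real_,
                estimate = c(mean(rates_a), mean(rates_b))))
  }
  ht <- stats::t.test(rates_a, rates_b, var.equal = FALSE)
  list(p_value = unname(ht$p.value), statistic = unname(ht$statistic),
       estimate = unname(ht$estimate))
}
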