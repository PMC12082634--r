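# scripted single-lipid trajectory: head/tail z series -> traj + lipid_set
scripted_lipid <- function(head_z, tail_z, box = c(10, 10, 12)) {
  nf <- length(head_z)
  coords <- array(5, dim = c(2, 3, nf))
  coords[1, 3, ] <- head_z
  coords[2, 3, ] <- tail_z
  traj <- trajectory(times = seq_len(nf) - 1, coords = coords, box = box,
                     atoms = data.frame(name = c("PO4", "C4B"),
                                        resname = "POPC", resid = 1))
  list(traj = traj, lipids = lipid_set(1L, "POPC", 1L, 2L))
}

test_that("all-undetermined orientations never change the assignment", {
  s <- scripted_lipid(head_z = rep(6, 20), tail_z = rep(6, 20))
  st <- assign_leaflets(s$traj, s$lipids)
  expect_true(all(st$inst == 0))
  expect_equal(length(unique(as.vector(st$assigned))), 1)
  expect_equal(nrow(detect_events(st, s$traj, s$lipids)), 0)
})

test_that("a scripted full crossing yields exactly one event with correct direction", {
  # head walks from upper plane to lower while the tail mirrors it
  head_z <- c(rep(8, 5), seq(8, 4, length.out = 6), rep(4, 5))
  tail_z <- c(rep(5, 5), seq(5, 9, length.out = 6), rep(9, 5))
  s <- scripted_lipid(head_z, tail_z)
  st <- assign_leaflets(s$traj, s$lipids)
  ev <- detect_events(st, s$traj, s$lipids)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$direction, "up_to_down")
  # hysteresis: an excursion to undetermined and back is not an event
  head_z2 <- c(rep(8, 5), rep(6.2, 5), rep(8, 5))
  tail_z2 <- c(rep(5, 5), rep(5.8, 5), rep(5, 5))
  s2 <- scripted_lipid(head_z2, tail_z2)
  st2 <- assign_leaflets(s2$traj, s2$lipids)
  expect_equal(nrow(detect_events(st2, s2$traj, s2$lipids)), 0)
})

test_that("assignment changes match generator ground truth events", {
  g <- small_system(n_frames = 1000, seed = 13)
  st <- assign_leaflets(g$traj, g$lipids)
  ev <- detect_events(st, g$traj, g$lipids)
  expect_equal(nrow(ev), nrow(g$events))
  # each detected event corresponds to one truth event of the same lipid,
  # detected within the transit window (plus one frame of slack)
  tr <- g$events
  dt <- g$traj$times[2] - g$traj$times[1]
  for (k in seq_len(nrow(ev))) {
    cand <- which(tr$lipid_id == ev$lipid_id[k])
    lag <- ev$time_ns[k] - tr$t_start_ns[cand]
    ok <- lag >= -dt & lag <= 50 + 2 * dt  # transit_ns = 50
    expect_true(any(ok))
    tr <- tr[-cand[which(ok)[1]], , drop = FALSE]
  }
  expect_equal(nrow(tr), 0)
  # directions alternate per lipid
  for (l in unique(ev$lipid_id)) {
    dirs <- ev$direction[ev$lipid_id == l]
    if (length(dirs) > 1) expect_true(all(dirs[-1] != dirs[-length(dirs)]))
  }
})

test_that("events are attributed to their true sites at the 2 nm cutoff", {
  g <- small_system(n_frames = 2000, seed = 17,
                    rates = list(POPC = c(Sec61 = 2, TRAP = 2)))
  st <- assign_leaflets(g$traj, g$lipids)
  ev <- detect_events(st, g$traj, g$lipids)
  ev <- assign_events_to_sites(ev, g$sites, g$traj, cutoff = 2.0)
  # match each detected event to the truth event of the same lipid closest in time
  truth_site <- vapply(seq_len(nrow(ev)), function(k) {
    cand <- g$events[g$events$lipid_id == ev$lipid_id[k], ]
    cand$site[which.min(abs(cand$t_start_ns - ev$time_ns[k]))]
  }, "")
  expect_gte(mean(ev$site == truth_site), 0.95)
  # no sites configured -> everything stays bulk
  ev0 <- assign_events_to_sites(detect_events(st, g$traj, g$lipids),
                                protein_sites(), g$traj)
  expect_true(all(ev0$site == "bulk"))
})

test_that("an event farther than the cutoff from all sites is bulk", {
  # one lipid crossing 2.5 nm away laterally from a site bead column
  head_z <- c(rep(8, 3), seq(8, 4, length.out = 5), rep(4, 3))
  tail_z <- c(rep(5, 3), seq(5, 9, length.out = 5), rep(9, 3))
  nf <- length(head_z)
  coords <- array(5, dim = c(3, 3, nf))
  coords[1, 3, ] <- head_z
  coords[2, 3, ] <- tail_z
  coords[3, , ] <- c(7.5, 5, 6)  # site bead at distance 2.5 in x
  coords[1, 1, ] <- 5; coords[2, 1, ] <- 5
  traj <- trajectory(seq_len(nf) - 1, coords, c(15, 15, 12),
                     data.frame(name = c("PO4", "C4B", "BB1"),
                                resname = c("POPC", "POPC", "SITE"),
                                resid = c(1, 1, 2)))
  lipids <- lipid_set(1L, "POPC", 1L, 2L)
  sites <- protein_sites(list(X = 3L))
  st <- assign_leaflets(traj, lipids)
  ev <- detect_events(st, traj, lipids)
  ev <- assign_events_to_sites(ev, sites, traj, cutoff = 2.0)
  expect_equal(ev$site, "bulk")
})

test_that("rate table arithmetic matches replica statistics", {
  mk_ev <- function(n) data.frame(lipid_id = seq_len(n),
                                  type = rep("POPC", n),
                                  time_ns = seq_len(n),
                                  direction = rep("up_to_down", n),
                                  x = numeric(n), y = numeric(n),
                                  z = numeric(n), site = rep("bulk", n))
  # five replicas each with exactly 154 events in 20 us -> 7.7 +/- 0.0
  rt5 <- compute_rates(rep(list(mk_ev(154)), 5), durations_us = 20)
  row <- rt5[rt5$site == "bulk" & rt5$lipid_type == "POPC", ]
  expect_equal(row$rate, 7.7)
  expect_equal(row$se, 0)
  expect_equal(row$total_events, 5L * 154L)
  # no events anywhere -> 0.0 +/- 0.0 rows
  rt0 <- compute_rates(rep(list(mk_ev(0)), 5), durations_us = 20,
                       sites = "bulk", types = "POPC")
  expect_true(all(rt0$rate == 0) && all(rt0$se == 0))
  expect_error(compute_rates(list(mk_ev(3)), durations_us = 0), "zero-duration")
})

test_that("rate estimator recovers the true Poisson rate within 3 SE", {
  reps <- lapply(1:5, function(r) {
    g <- small_system(rates = list(POPC = c(Sec61 = 2.2)), n_frames = 1000,
                      seed = 100 + r)
    st <- assign_leaflets(g$traj, g$lipids)
    ev <- detect_events(st, g$traj, g$lipids)
    assign_events_to_sites(ev, g$sites, g$traj)
  })
  tab <- compute_rates(reps, durations_us = 10)
  row <- tab[tab$site == "Sec61" & tab$lipid_type == "POPC", ]
  expect_lt(abs(row$rate - 2.2), 3 * max(row$se, sqrt(2.2 / 10) / sqrt(5)))
})

test_that("threshold scan is flat over the clean-data plateau", {
  g <- small_system(n_frames = 1000, seed = 23,
                    rates = list(POPC = c(Sec61 = 2)))
  th <- seq(1.0, 3.4, by = 0.2)
  sc <- threshold_scan(g$traj, g$lipids, th)
  expect_true(all(diff(sc$scan$n_events) <= 0))
  plateau_rates <- sc$scan$rate[sc$scan$threshold >= 1.8 &
                                  sc$scan$threshold <= 2.6]
  expect_equal(length(unique(plateau_rates)), 1)
  expect_true(sc$plateau[1] <= 1.8 && sc$plateau[2] >= 2.6)
  # threshold above any |dz| -> zero events
  sc_hi <- threshold_scan(g$traj, g$lipids, 5.0)
  expect_equal(sc_hi$scan$n_events, 0L)
})

test_that("arrhenius fit matches closed form and flags bad input", {
  EA <- 42; lnA <- 18
  temps <- seq(280, 340, 10)
  k <- exp(lnA - EA / (8.314462618e-3 * temps))
  fit <- fit_arrhenius(temps, k)
  expect_equal(fit$E_A, EA, tolerance = 1e-9)
  expect_equal(fit$lnA, lnA, tolerance = 1e-9)
  expect_equal(fit_arrhenius(temps, rep(2, 7))$E_A, 0, tolerance = 1e-12)
  expect_error(fit_arrhenius(c(300, 310), c(1, 2)), "3 distinct")
  expect_error(fit_arrhenius(temps, c(0, k[-1])), "> 0")
  # weighted mode runs and stays near the unweighted answer on clean data
  fw <- fit_arrhenius(temps, k, se = 0.05 * k, weighted = TRUE)
  expect_equal(fw$E_A, EA, tolerance = 1e-6)
})

test_that("eyring calculators obey their identities", {
  expect_equal(eyring_speedup(10, 10, 310), 1)
  # fold change equals the ratio of eyring rates exactly
  expect_equal(eyring_speedup(59.2, 9.4, 310),
               eyring_rate(9.4, 310) / eyring_rate(59.2, 310))
  # strictly decreasing in the new barrier
  folds <- eyring_speedup(50, c(5, 10, 20, 40), 310)
  expect_true(all(diff(folds) < 0))
  # a month-scale half-life shrinks to tens of ms at 2.5e8-fold
  expect_equal(scaled_half_life(30 * 24 * 3600, 2.5e8), 30 * 24 * 3600 / 2.5e8)
})

test_that("rate comparison behaves like a Welch test", {
  expect_equal(compare_rates(c(2, 2, 2), c(2, 2, 2))$p_value, 1)
  # clearly separated groups
  p <- compare_rates(c(6.5, 6.1, 6.9, 6.4, 6.6), c(2.2, 2.0, 2.4, 2.3, 2.1))$p_value
  expect_lt(p, 0.01)
  # agrees with stats::t.test on generic data
  a <- c(3.1, 2.8, 3.5, 3.0); b <- c(2.2, 2.6, 2.0, 2.4)
  expect_equal(compare_rates(a, b)$p_value,
               stats::t.test(a, b)$p.value)
  expect_error(compare_rates(1, c(1, 2)), "2 replicas")
})

test_that("type-I error of the rate comparison is near nominal", {
  set.seed(31)
  rejections <- 0
  n_sim <- 400
  for (i in seq_len(n_sim)) {
    a <- rpois(5, 40) / 20
    b <- rpois(5, 40) / 20
    p <- compare_rates(a, b)$p_value
    if (p < 0.05) rejections <- rejections + 1
  }
  # binomial 3-sigma band around 0.05
  expect_lt(abs(rejections / n_sim - 0.05), 3 * sqrt(0.05 * 0.95 / n_sim) + 0.01)
})

test_that("two independent sites sum to the combined-system rate", {
  rate_of <- function(rates, seed) {
    g <- small_system(rates = list(POPC = rates), n_frames = 2000, seed = seed)
    st <- assign_leaflets(g$traj, g$lipids)
    nrow(detect_events(st, g$traj, g$lipids)) / 20
  }
  k_a <- mean(vapply(1:3, function(s) rate_of(c(Sec61 = 1.5), 40 + s), 0))
  k_b <- mean(vapply(1:3, function(s) rate_of(c(TRAP = 0.8), 50 + s), 0))
  k_ab <- mean(vapply(1:3, function(s) rate_of(c(Sec61 = 1.5, TRAP = 0.8),
                                               60 + s), 0))
  se <- sqrt((1.5 + 0.8) / 20 / 3)  # Poisson SE of the mean of 3 replicas
  expect_lt(abs(k_ab - (k_a + k_b)), 4 * se)
})
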