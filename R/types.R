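#' Construct a trajectory object
#'
#' The central container for all trajectory analyses: per-frame particle
#' coordinates in an orthorhombic box, with frame times and per-particle
#' metadata. Units are nm (coordinates, box) and ns (times) throughout.
#'
#' @param times numeric vector of frame times (ns), strictly increasing.
#' @param coords numeric array of dimension `c(n_atoms, 3, n_frames)` (nm).
#' @param box numeric matrix `n_frames x 3` of orthorhombic box edge
#'   lengths (nm), or a length-3 vector recycled to all frames.
#' @param atoms data frame with columns `name`, `resname`, `resid` and
#'   optionally `chain`, one row per particle.
#' @return an object of class `"traj"`.
#' @export
trajectory <- function(times, coords, box, atoms) {
  times <- as.numeric(times)
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing")
  }
  if (length(dim(coords)) != 3 || dim(coords)[2] != 3) {
    stop("coords must be an n_atoms x 3 x n_frames array")
  }
  n_frames <- dim(coords)[3]
  n_atoms <- dim(coords)[1]
  if (length(times) != n_frames) {
    stop("length(times) must equal the number of frames")
  }
  if (is.null(dim(box))) {
    box <- matrix(rep(as.numeric(box), each = n_frames), nrow = n_frames)
  }
  box <- as.matrix(box)
  if (nrow(box) != n_frames || ncol(box) != 3) {
    stop("box must be n_frames x 3")
  }
  if (any(box <= 0)) stop("all box lengths must be > 0")
  atoms <- as.data.frame(atoms)
  if (!all(c("name", "resname", "resid") %in% names(atoms))) {
    stop("atoms must have columns name, resname, resid")
  }
  if (nrow(atoms) != n_atoms) {
    stop("nrow(atoms) must match the number of particles in coords")
  }
  if (is.null(atoms$chain)) atoms$chain <- NA_character_
  structure(list(times = times, coords = coords, box = box, atoms = atoms),
            class = "traj")
}

#' @export
print.traj <- function(x, ...) {
  cat(sprintf("<traj> %d particles, %d frames, t = %.6g..%.6g ns\n",
              dim(x$coords)[1], length(x$times),
              x$times[1], x$times[length(x$times)]))
  cat(sprintf("  box (frame 1): %.3f x %.3f x %.3f nm\n",
              x$box[1, 1], x$box[1, 2], x$box[1, 3]))
  invisible(x)
}

#' Number of frames / particles in a trajectory
#' @param traj a [trajectory()] object.
#' @return integer count.
#' @export
n_frames <- function(traj) length(traj$times)

#' @rdname n_frames
#' @export
n_particles <- function(traj) dim(traj$coords)[1]

#' Bead selection map
#'
#' Declares, per lipid type, which bead tracks the headgroup (e.g. the
#' Martini phosphate bead "PO4") and which the acyl-chain terminus (e.g.
#' "C4B"), plus optional protein-group selectors and the membrane-frame
#' reference selector.
#'
#' @param lipids named list; each element `list(head = "PO4", tail = "C4B")`,
#'   named by lipid residue name (e.g. `"POPC"`).
#' @param proteins named list of selector lists; each selector has fields
#'   `res_start`, `res_end` and optionally `chain` and/or `resname`.
#' @param reference a single selector (same fields) for the membrane-frame
#'   reference group, or `NULL`.
#' @return object of class `"bead_selection_map"`.
#' @export
bead_selection_map <- function(lipids, proteins = list(), reference = NULL) {
  stopifnot(is.list(lipids), length(lipids) >= 1, !is.null(names(lipids)))
  for (nm in names(lipids)) {
    l <- lipids[[nm]]
    if (!is.list(l) || is.null(l$head) || is.null(l$tail) ||
        length(l$head) != 1 || length(l$tail) != 1) {
      stop("lipid type '", nm, "' must map to exactly one head and one tail bead")
    }
  }
  for (nm in names(proteins)) {
    p <- proteins[[nm]]
    if (is.null(p$res_start) || is.null(p$res_end) || p$res_start > p$res_end) {
      stop("protein selector '", nm, "' needs a non-empty residue range with start <= end")
    }
  }
  structure(list(lipids = lipids, proteins = proteins, reference = reference),
            class = "bead_selection_map")
}

#' Lipid set: head/tail particle indices per lipid
#'
#' @param lipid_id integer lipid identifiers (unique).
#' @param type character lipid type per lipid.
#' @param head,tail particle indices (1-based) of the head and tail beads.
#' @param n_atoms optional particle count for index validation.
#' @return data frame of class `c("lipid_set", "data.frame")`.
#' @export
lipid_set <- function(lipid_id, type, head, tail, n_atoms = NULL) {
  if (any(head == tail)) stop("head and tail indices must differ")
  if (anyDuplicated(lipid_id)) stop("lipid ids must be unique")
  if (!is.null(n_atoms) && any(c(head, tail) > n_atoms | c(head, tail) < 1)) {
    stop("head/tail indices out of range for the trajectory")
  }
  structure(data.frame(lipid_id = lipid_id, type = as.character(type),
                       head = as.integer(head), tail = as.integer(tail)),
            class = c("lipid_set", "data.frame"))
}

#' Protein scrambling sites
#'
#' Named protein sites ("Sec61", "TRAP", ...), each a set of particle
#' indices of its pathway-defining beads, plus the membrane-frame
#' reference group.
#'
#' @param sites named list of integer vectors (particle indices).
#' @param reference integer vector of reference-group particle indices.
#' @return object of class `"protein_sites"`.
#' @export
protein_sites <- function(sites = list(), reference = integer()) {
  if (length(sites) > 0) {
    if (is.null(names(sites)) || anyDuplicated(names(sites))) {
      stop("sites must be uniquely named")
    }
    if (any(vapply(sites, length, 1L) == 0)) {
      stop("configuration error: empty site bead set")
    }
  }
  structure(list(sites = lapply(sites, as.integer),
                 reference = as.integer(reference)),
            class = "protein_sites")
}

#' Replica set
#'
#' A collection of replica simulations sharing one topology, used for
#' rate statistics and temperature series.
#'
#' @param replicas list of entries, each a list with fields `traj`
#'   (a [trajectory()] or `NULL` when rates are supplied externally),
#'   `temperature` (K), `composition` (label), `replica` (index) and
#'   `duration_us`.
#' @return object of class `"replica_set"`.
#' @export
replica_set <- function(replicas) {
  stopifnot(is.list(replicas), length(replicas) >= 1)
  np <- NULL
  for (r in replicas) {
    if (is.null(r$temperature) || r$temperature <= 0) {
      stop("all replica temperatures must be > 0")
    }
    if (!is.null(r$traj)) {
      if (is.null(np)) np <- n_particles(r$traj)
      if (n_particles(r$traj) != np) stop("all replicas must share one topology")
    }
  }
  structure(replicas, class = "replica_set")
}

#' One-dimensional profile on a uniform z grid
#'
#' @param z grid of bin centres (nm), uniformly spaced.
#' @param values numeric values, one per bin.
#' @param unit unit label for the values.
#' @param error optional per-bin error, same length.
#' @return object of class `"profile1d"`.
#' @export
profile1d <- function(z, values, unit = "", error = NULL) {
  z <- as.numeric(z); values <- as.numeric(values)
  if (length(z) != length(values)) stop("grid and value lengths must match")
  if (length(z) >= 3) {
    dz <- diff(z)
    if (max(abs(dz - dz[1])) > 1e-9) stop("z grid must be uniform (tolerance 1e-9 nm)")
    if (dz[1] <= 0) stop("z grid must be increasing")
  }
  if (!is.null(error)) {
    if (length(error) != length(z)) stop("error length must match grid")
    if (any(error < 0, na.rm = TRUE)) stop("per-bin errors must be >= 0")
  }
  structure(list(z = z, values = values, unit = unit, error = error),
            class = "profile1d")
}

#' @export
print.profile1d <- function(x, ...) {
  cat(sprintf("<profile1d> %d bins, z = %.4g..%.4g nm [%s]\n",
              length(x$z), x$z[1], x$z[length(x$z)], x$unit))
  invisible(x)
}

#' Scrambling rate table
#'
#' Per-site, per-lipid-type scrambling rates with replica standard
#' errors, mirroring the layout of a per-system rate summary.
#'
#' @param site,lipid_type character labels.
#' @param rate,se rates and standard errors in 1/us.
#' @param n_replicas replica count used per row.
#' @param total_events event count summed over replicas.
#' @return data frame of class `c("rate_table", "data.frame")`.
#' @export
rate_table <- function(site, lipid_type, rate, se, n_replicas, total_events) {
  if (any(rate < 0) || any(se < 0)) stop("rates and SEs must be >= 0")
  if (any(n_replicas < 1)) stop("n_replicas must be >= 1")
  structure(data.frame(site = site, lipid_type = lipid_type,
                       rate = rate, se = se,
                       n_replicas = as.integer(n_replicas),
                       total_events = as.integer(total_events)),
            class = c("rate_table", "data.frame"))
}

#' @export
print.rate_table <- function(x, ...) {
  y <- as.data.frame(x)
  # one-decimal rate formatting, matching the field's summary-table convention
  y$rate_1_us <- sprintf("%.1f ± %.1f", y$rate, y$se)
  print(y[, c("site", "lipid_type", "rate_1_us", "n_replicas", "total_events")],
        row.names = FALSE)
  invisible(x)
}
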