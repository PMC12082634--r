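#' Read a (possibly multi-frame) GRO coordinate file
#'
#' Parses the fixed-column GROMACS GRO dialect (coordinates in nm,
#' optional velocity columns ignored). Frame times are taken from a
#' `t=` tag on the title line when present, otherwise frames are
#' numbered 0, 1, 2, ... ns. Only orthorhombic boxes are supported;
#' a box line with non-zero off-diagonal components is rejected.
#'
#' @param path path to a GRO file.
#' @return a [trajectory()] object.
#' @export
read_gro <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) stop("format error: GRO file too short at line 1")
  frames <- list()
  i <- 1L
  frame_idx <- 0L
  atoms_meta <- NULL
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    title <- lines[i]
    if (i + 1L > length(lines)) {
      stop("I/O error: truncated frame ", frame_idx + 1L, " at line ", i)
    }
    nat <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(nat) || nat < 1) {
      stop("format error: invalid atom count at line ", i + 1L)
    }
    if (i + 1L + nat + 1L > length(lines)) {
      stop("I/O error: truncated frame ", frame_idx + 1L, " at line ", i)
    }
    al <- lines[(i + 2L):(i + 1L + nat)]
    xyz <- .parse_gro_atoms(al, first_line = i + 2L)
    box <- .parse_gro_box(lines[i + 1L + nat + 1L], line_no = i + 1L + nat + 1L)
    tm <- .parse_gro_time(title)
    if (is.na(tm)) tm <- as.numeric(frame_idx)
    if (is.null(atoms_meta)) {
      atoms_meta <- xyz$meta
    } else if (nrow(xyz$meta) != nrow(atoms_meta)) {
      stop("topology error: particle count changed at frame ", frame_idx + 1L)
    }
    frames[[frame_idx + 1L]] <- list(time = tm, coords = xyz$coords, box = box)
    frame_idx <- frame_idx + 1L
    i <- i + 2L + nat + 1L
  }
  if (frame_idx == 0L) stop("format error: no frames found")
  n_atoms <- nrow(atoms_meta)
  coords <- array(NA_real_, dim = c(n_atoms, 3L, frame_idx))
  box <- matrix(NA_real_, nrow = frame_idx, ncol = 3L)
  times <- numeric(frame_idx)
  for (f in seq_len(frame_idx)) {
    coords[, , f] <- frames[[f]]$coords
    box[f, ] <- frames[[f]]$box
    times[f] <- frames[[f]]$time
  }
  trajectory(times = times, coords = coords, box = box, atoms = atoms_meta)
}

.parse_gro_time <- function(title) {
  m <- regmatches(title, regexpr("t=\\s*[-+0-9.eE]+", title))
  if (length(m) == 0) return(NA_real_)
  # GRO titles carry time in ps; convert to the package's ns convention
  as.numeric(sub("t=\\s*", "", m)) / 1000
}

.parse_gro_atoms <- function(al, first_line) {
  resid <- suppressWarnings(as.integer(substr(al, 1L, 5L)))
  resname <- trimws(substr(al, 6L, 10L))
  name <- trimws(substr(al, 11L, 15L))
  x <- suppressWarnings(as.numeric(substr(al, 21L, 28L)))
  y <- suppressWarnings(as.numeric(substr(al, 29L, 36L)))
  z <- suppressWarnings(as.numeric(substr(al, 37L, 44L)))
  bad <- which(is.na(resid) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad) > 0) {
    stop("format error: unparsable atom record at line ", first_line + bad[1] - 1L)
  }
  list(coords = cbind(x, y, z),
       meta = data.frame(name = name, resname = resname, resid = resid,
                         chain = NA_character_))
}

.parse_gro_box <- function(line, line_no) {
  v <- suppressWarnings(as.numeric(strsplit(trimws(line), "\\s+")[[1]]))
  if (any(is.na(v)) || !(length(v) %in% c(3L, 9L))) {
    stop("format error: invalid box line at line ", line_no)
  }
  if (length(v) == 9L && any(abs(v[4:9]) > 1e-9)) {
    stop("unsupported feature: triclinic box (only orthorhombic boxes are supported)")
  }
  v[1:3]
}

#' Write a trajectory as a (multi-frame) GRO file
#'
#' Fixed-column GRO with 3-decimal (0.001 nm) coordinate precision; one
#' concatenated frame per time point. Round-trips through [read_gro()]
#' with positions equal to that precision and times exact.
#'
#' @param traj a [trajectory()] object.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gro <- function(traj, path) {
  if (!inherits(traj, "traj")) stop("traj must be a trajectory object")
  if (n_frames(traj) < 1) stop("cannot write an empty trajectory")
  a <- traj$atoms
  n <- nrow(a)
  con <- file(path, "w")
  on.exit(close(con))
  atomnr <- seq_len(n) %% 100000L
  residw <- a$resid %% 100000L
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("scramblekit frame %d t= %.6f", f - 1L,
                       traj$times[f] * 1000), con)
    writeLines(sprintf("%5d", n), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       residw, a$resname, a$name, atomnr,
                       traj$coords[, 1, f], traj$coords[, 2, f],
                       traj$coords[, 3, f]), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f",
                       traj$box[f, 1], traj$box[f, 2], traj$box[f, 3]), con)
  }
  invisible(path)
}

#' Read a structure or trajectory file into a trajectory object
#'
#' Dispatches on extension: `.gro` (single or multi frame, nm) or `.pdb`
#' (via the bio3d reader; coordinates converted from Angstrom to nm).
#' Binary XTC/TRR input is not supported; convert to multi-frame GRO
#' upstream (e.g. `gmx trjconv`).
#'
#' @param path input file.
#' @param n_expected optional particle count to validate against.
#' @return a [trajectory()] object.
#' @export
read_trajectory <- function(path, n_expected = NULL) {
  ext <- tolower(tools::file_ext(path))
  traj <- switch(ext,
    gro = read_gro(path),
    pdb = .read_pdb_traj(path),
    xtc = ,
    trr = stop("unsupported feature: binary ", toupper(ext),
               " input; convert to multi-frame GRO first"),
    stop("format error: unrecognised trajectory extension '", ext, "'"))
  if (!is.null(n_expected) && n_particles(traj) != n_expected) {
    stop("topology error: file has ", n_particles(traj),
         " particles, expected ", n_expected)
  }
  sk_log("read ", n_frames(traj), " frames / ", n_particles(traj),
         " particles from ", path)
  traj
}

.read_pdb_traj <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("reading PDB requires the bio3d package")
  }
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  coords <- array(c(at$x, at$y, at$z) / 10, dim = c(nrow(at), 3L, 1L))
  # PDB carries no box for our purposes unless CRYST1 present; fall back
  # to the coordinate extent so downstream wrapping stays valid
  box <- apply(coords[, , 1, drop = FALSE], 2, function(v) max(v) - min(v) + 1)
  trajectory(times = 0, coords = coords, box = pmax(box, 1),
             atoms = data.frame(name = at$elety, resname = at$resid,
                                resid = at$resno, chain = at$chain))
}

#' @rdname write_gro
#' @export
write_trajectory <- function(traj, path) write_gro(traj, path)

#' Resolve lipid head/tail beads and protein sites from a structure
#'
#' Applies a [bead_selection_map()] to the particle metadata of a
#' structure file (or an already-read trajectory): every residue whose
#' residue name matches a mapped lipid type must contain exactly the
#' named head and tail beads; protein selectors resolve by residue range
#' (and chain/residue name when given).
#'
#' @param x path to a GRO/PDB file, or a [trajectory()] object.
#' @param selmap a [bead_selection_map()].
#' @return list with elements `lipids` (a [lipid_set()]) and
#'   `sites` (a [protein_sites()]).
#' @export
read_topology <- function(x, selmap) {
  if (!inherits(selmap, "bead_selection_map")) {
    stop("selmap must be a bead_selection_map")
  }
  traj <- if (inherits(x, "traj")) x else read_trajectory(x)
  a <- traj$atoms
  ids <- integer(); types <- character(); heads <- integer(); tails <- integer()
  lip_id <- 0L
  for (type in names(selmap$lipids)) {
    sel <- selmap$lipids[[type]]
    rows <- which(a$resname == type)
    if (length(rows) == 0) next
    for (rid in unique(a$resid[rows])) {
      rr <- rows[a$resid[rows] == rid]
      h <- rr[a$name[rr] == sel$head]
      t <- rr[a$name[rr] == sel$tail]
      if (length(h) != 1 || length(t) != 1) {
        stop("selection error: lipid residue ", rid, " (", type,
             ") lacks a unique ", sel$head, "/", sel$tail, " bead pair")
      }
      lip_id <- lip_id + 1L
      ids <- c(ids, lip_id); types <- c(types, type)
      heads <- c(heads, h); tails <- c(tails, t)
    }
  }
  if (lip_id == 0L) stop("selection error: no lipids of any mapped type found")
  sites <- list()
  for (nm in names(selmap$proteins)) {
    p <- selmap$proteins[[nm]]
    idx <- .resolve_selector(a, p)
    if (length(idx) == 0) {
      warning("unresolved protein selector '", nm, "'")
    } else {
      sites[[nm]] <- idx
    }
  }
  ref <- integer()
  if (!is.null(selmap$reference)) {
    ref <- .resolve_selector(a, selmap$reference)
  }
  list(lipids = lipid_set(ids, types, heads, tails, n_atoms = nrow(a)),
       sites = protein_sites(sites, reference = ref))
}

.resolve_selector <- function(atoms, sel) {
  keep <- atoms$resid >= sel$res_start & atoms$resid <= sel$res_end
  if (!is.null(sel$resname)) keep <- keep & atoms$resname %in% sel$resname
  if (!is.null(sel$chain) && !all(is.na(atoms$chain))) {
    keep <- keep & atoms$chain %in% sel$chain
  }
  which(keep)
}

#' Read a two-column tabular profile (XVG dialect)
#'
#' Whitespace-separated numeric columns; lines starting with `#` or `@`
#' are ignored, so AWH/gmx XVG output can be ingested directly.
#'
#' @param path input file.
#' @param unit unit label to attach to the values.
#' @return a [profile1d()].
#' @export
read_tabular_profile <- function(path, unit = "kJ/mol") {
  lines <- readLines(path)
  keep <- !grepl("^\\s*[#@]", lines) & nzchar(trimws(lines))
  ln_no <- which(keep)
  rows <- strsplit(trimws(lines[keep]), "\\s+")
  z <- numeric(length(rows)); v <- numeric(length(rows))
  for (k in seq_along(rows)) {
    num <- suppressWarnings(as.numeric(rows[[k]][1:2]))
    if (length(rows[[k]]) < 2 || any(is.na(num))) {
      stop("parse error: non-numeric payload at line ", ln_no[k])
    }
    z[k] <- num[1]; v[k] <- num[2]
  }
  if (length(z) > 1 && any(diff(z) <= 0)) stop("grid must be strictly increasing")
  profile1d(z, v, unit = unit)
}

#' Write a profile as two-column text
#'
#' @param profile a [profile1d()].
#' @param path output path.
#' @param header optional comment lines (written with a leading `#`).
#' @return invisibly, `path`.
#' @export
write_tabular_profile <- function(profile, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines(sprintf("%.10g %.10g", profile$z, profile$values), con)
  invisible(path)
}

#' Read a fluorescence assay curve from CSV
#'
#' Expects the header `time_s,intensity`.
#'
#' @param path CSV file path.
#' @return data frame with columns `time_s`, `intensity`.
#' @export
read_assay_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "intensity") %in% names(d))) {
    stop("format error: assay CSV must have header 'time_s,intensity'")
  }
  d
}

#' Read a run configuration (YAML or JSON)
#'
#' Unspecified fields fall back to the package defaults: leaflet
#' threshold 2.1 nm, pathway cutoff 2.0 nm, bulk exclusion 3.0 nm.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return named list of configuration values.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("format error: config must be YAML or JSON")
  }
  defaults <- list(leaflet_threshold_nm = 2.1, pathway_cutoff_nm = 2.0,
                   bulk_exclusion_nm = 3.0, leaflet_sign = 1, seed = 1L)
  out <- utils::modifyList(defaults, cfg)
  sk_log("resolved config: ", paste(names(out), unlist(out),
                                    sep = "=", collapse = " "))
  out
}

#' Package logging
#'
#' Timestamped messages on stderr; set `options(scramblekit.quiet = TRUE)`
#' to silence, `options(scramblekit.logfile = path)` to tee to a file.
#'
#' @param ... message parts, concatenated.
#' @return invisibly, the formatted line.
#' @export
sk_log <- function(...) {
  line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " [scramblekit] ",
                 paste0(..., collapse = ""))
  if (!isTRUE(getOption("scramblekit.quiet", FALSE))) message(line)
  lf <- getOption("scramblekit.logfile")
  if (!is.null(lf)) cat(line, "\n", file = lf, append = TRUE)
  invisible(line)
}
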